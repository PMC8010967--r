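## Seeded generators producing FASTA + site-annotation + structure-table
## inputs with controllable class structure, so every pipeline stage is
## testable without external downloads.

## Window positions (relative to the central lysine) that carry the
## class-specific residue signal; chosen to echo the informative positional
## effects the pipeline is meant to recover.
FIXTURE_SIGNAL_POSITIONS <- c(-4L, -1L, 2L, 4L, 7L)

#' Specification of a synthetic multi-class fixture
#'
#' Describes a set of synthetic proteins, each embedding one annotated
#' central lysine whose flanking residues are drawn from a class-specific
#' position-specific distribution: with probability `motif_strength` an
#' informative flank position shows the class's preferred residue,
#' otherwise a uniform residue. Structural channels are drawn from
#' class-shifted Gaussians (`structure_effect` standard deviations between
#' the extreme classes), with Q3/Q8 blocks as softmax probabilities.
#'
#' @param counts named or plain integer vector of per-class sample counts;
#'   names become class (modification) names. Default: the seven-class
#'   reference counts of [paper_counts_fixture()].
#' @param motif_strength per-position probability (in \[0, 1\]) of the
#'   class-preferred residue at informative positions; default 0.5.
#' @param structure_effect class separation of the structural channels in
#'   standard deviations; default 0.8.
#' @param noise multiplier on all structural channel standard deviations.
#' @param xi flank width; default 8 (17-mers).
#' @param seed RNG seed; fixture files are byte-identical for equal seeds.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(counts = NULL, motif_strength = 0.5,
                         structure_effect = 0.8, noise = 1, xi = 8,
                         seed = 1L) {
  if (is.null(counts)) return(paper_counts_fixture(motif_strength = motif_strength,
                                                   structure_effect = structure_effect,
                                                   noise = noise, xi = xi,
                                                   seed = seed))
  stopifnot(all(counts >= 1), motif_strength >= 0, motif_strength <= 1)
  if (is.null(names(counts)))
    names(counts) <- paste0("Mod", LETTERS[seq_along(counts)])
  structure(list(counts = counts, motif_strength = motif_strength,
                 structure_effect = structure_effect, noise = noise,
                 xi = xi, seed = seed),
            class = "fixture_spec")
}

#' Fixture specification with the seven reference class counts
#'
#' The seven lysine-modification classes in lexicographic order with their
#' reference sample counts: Ace 3114, Glyca 1399, Malon 1224, Meth 1147,
#' Succ 1645, Sumo 1174, Ubiq 3185 (total 12888). Used for balancing
#' arithmetic and scaled-down pipeline runs.
#'
#' @inheritParams fixture_spec
#' @return a `fixture_spec`.
#' @export
paper_counts_fixture <- function(motif_strength = 0.5, structure_effect = 0.8,
                                 noise = 1, xi = 8, seed = 1L) {
  fixture_spec(counts = c(Ace = 3114L, Glyca = 1399L, Malon = 1224L,
                          Meth = 1147L, Succ = 1645L, Sumo = 1174L,
                          Ubiq = 3185L),
               motif_strength = motif_strength,
               structure_effect = structure_effect, noise = noise, xi = xi,
               seed = seed)
}

## Distinct preferred flank residue per class (lysine excluded).
fixture_preferred_residues <- function(K) {
  pool <- setdiff(AA_ALPHABET, "K")
  if (K > length(pool)) stop("too many classes for distinct preferred residues")
  pool[seq_len(K)]
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' Generate a synthetic fixture
#'
#' Produces, in memory and optionally on disk, the three input files the
#' pipeline consumes: a protein FASTA (one protein per sample, central
#' lysine at a fixed position), a site-annotation TSV and a per-residue
#' structure TSV covering each annotated window. Fully reproducible from
#' the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; when given, writes
#'   `proteins.fasta`, `sites.tsv` and `structure.tsv` there.
#' @return a list with `proteins` (named character), `sites`, `structure`
#'   data frames, `spec`, and `paths` when `dir` was given.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  counts <- spec$counts
  K <- length(counts)
  classes <- names(counts)
  prefs <- fixture_preferred_residues(K)
  xi <- spec$xi
  L <- 2L * xi + 1L
  outer_flank <- 10L
  site_pos <- outer_flank + xi + 1L
  prot_len <- L + 2L * outer_flank
  n_total <- sum(counts)
  rel <- seq_len(L) - xi - 1L   # window positions relative to the lysine

  proteins <- character(n_total)
  ids <- character(n_total)
  cls <- rep(classes, counts)
  # class offsets in [-1, 1] drive the structural mean shifts
  s_off <- if (K > 1) 2 * (match(cls, classes) - 1) / (K - 1) - 1 else rep(0, n_total)

  struct_list <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    k <- match(cls[i], classes)
    win <- sample(AA_ALPHABET, L, replace = TRUE)
    win[xi + 1L] <- "K"
    for (p in FIXTURE_SIGNAL_POSITIONS) {
      j <- which(rel == p)
      if (stats::runif(1) < spec$motif_strength) win[j] <- prefs[k]
    }
    flank1 <- paste(sample(AA_ALPHABET, outer_flank, replace = TRUE), collapse = "")
    flank2 <- paste(sample(AA_ALPHABET, outer_flank, replace = TRUE), collapse = "")
    proteins[i] <- paste0(flank1, paste(win, collapse = ""), flank2)
    ids[i] <- sprintf("SYN%06d", i)
    struct_list[[i]] <- fixture_structure_rows(ids[i],
                                               (site_pos - xi):(site_pos + xi),
                                               s_off[i], spec)
  }
  names(proteins) <- ids
  sites <- data.frame(protein_id = ids, position = site_pos,
                      modification = cls, stringsAsFactors = FALSE)
  structure_tab <- do.call(rbind, struct_list)
  out <- list(proteins = proteins, sites = sites, structure = structure_tab,
              spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "proteins.fasta")
    aa <- Biostrings::AAStringSet(proteins)
    Biostrings::writeXStringSet(aa, fasta, width = 60)
    sites_path <- file.path(dir, "sites.tsv")
    utils::write.table(sites, sites_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    struct_path <- file.path(dir, "structure.tsv")
    utils::write.table(structure_tab, struct_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- c(fasta = fasta, sites = sites_path, structure = struct_path)
  }
  out
}

## 19 structural channels for the residues of one window; class offset
## s (in [-1, 1]) shifts means by structure_effect * s in channel units.
fixture_structure_rows <- function(protein_id, positions, s, spec) {
  n <- length(positions)
  eff <- spec$structure_effect * s
  nz <- spec$noise
  ss3 <- t(vapply(seq_len(n), function(i)
    softmax(stats::rnorm(3, sd = nz) + c(2 * eff, 0, 0)), numeric(3)))
  ss8 <- t(vapply(seq_len(n), function(i)
    softmax(stats::rnorm(8, sd = nz) + c(2 * eff, rep(0, 7))), numeric(8)))
  data.frame(
    protein_id = protein_id, position = positions,
    asa = stats::rnorm(n, 50 + 12 * eff, 12 * nz),
    ss3_H = ss3[, 1], ss3_E = ss3[, 2], ss3_C = ss3[, 3],
    ss8_G = ss8[, 1], ss8_H = ss8[, 2], ss8_I = ss8[, 3], ss8_B = ss8[, 4],
    ss8_E = ss8[, 5], ss8_T = ss8[, 6], ss8_S = ss8[, 7], ss8_C = ss8[, 8],
    phi = stats::rnorm(n, -60 + 40 * eff, 40 * nz),
    psi = stats::rnorm(n, -45 + 40 * eff, 40 * nz),
    theta = stats::rnorm(n, 100 + 30 * eff, 30 * nz),
    tau = stats::rnorm(n, 170 + 30 * eff, 30 * nz),
    hse_up = stats::rnorm(n, 15 + 5 * eff, 5 * nz),
    hse_down = stats::rnorm(n, 15 + 5 * eff, 5 * nz),
    cn = stats::rnorm(n, 30 + 8 * eff, 8 * nz),
    stringsAsFactors = FALSE)
}
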