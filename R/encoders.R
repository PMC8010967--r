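## Feature encoders: each turns a 17-residue lysine-centered fragment into
## a fixed-dimension numeric block with per-column human-readable tags.
## Block dimensions for L = 17:
##   AAindex 14L = 238, CKSAAP 3*400 = 1200, PWM L = 17,
##   ReducedAlphabet 8L = 136, FoldAmyloid L = 17, BE 20L = 340,
##   PC-PseAAC 20+lambda = 36, SC-PseAAC 20+2*lambda = 52,
##   Structure 19L = 323; total 2359.

feature_block <- function(scheme, values, tags) {
  stopifnot(length(values) == length(tags))
  structure(list(scheme = scheme, values = as.numeric(values),
                 tags = as.character(tags)),
            class = "feature_block")
}

## Window positions labelled relative to the central lysine: -8 .. +8.
position_labels <- function(L) {
  xi <- (L - 1L) %/% 2L
  p <- seq_len(L) - xi - 1L
  ifelse(p > 0, paste0("+", p), as.character(p))
}

#' Encode a fragment with 14 physicochemical AAindex profiles
#'
#' Position-major layout: the 14 property values of residue 1, then of
#' residue 2, and so on (14L = 238 dimensions for a 17-mer).
#'
#' @param sequence a fragment string of canonical residues.
#' @param properties residues x properties matrix (default
#'   [aaindex_properties()], z-scored).
#' @return a `feature_block`.
#' @export
encode_aaindex <- function(sequence, properties = aaindex_properties()) {
  chars <- seq_chars(sequence)
  check_canonical(chars)
  vals <- t(properties[chars, , drop = FALSE])   # properties x L
  pos <- position_labels(length(chars))
  tags <- as.vector(vapply(pos, function(p) paste0(colnames(properties), "@", p),
                           character(ncol(properties))))
  feature_block("AAindex", as.vector(vals), tags)
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each gap k in `k_set`, counts ordered residue pairs (i, i+k+1) and
#' normalises by the number of such pairs (L-1-k), giving 400 frequencies
#' per k over the alphabetical pair grid; blocks are concatenated k-major
#' (3 x 400 = 1200 dimensions for the default k in \{0, 1, 2\}).
#'
#' @param sequence fragment string.
#' @param k_set integer gaps; default `0:2`.
#' @return a `feature_block`.
#' @export
encode_cksaap <- function(sequence, k_set = 0:2) {
  chars <- seq_chars(sequence)
  check_canonical(chars)
  L <- length(chars)
  if (any(k_set >= L - 1)) stop("gap k must be < L - 1")
  idx <- match(chars, AA_ALPHABET)
  vals <- numeric(0); tags <- character(0)
  for (k in k_set) {
    npairs <- L - 1L - k
    a <- idx[seq_len(npairs)]
    b <- idx[seq_len(npairs) + k + 1L]
    counts <- numeric(400)
    tab <- table((a - 1L) * 20L + b)
    counts[as.integer(names(tab))] <- as.integer(tab)
    vals <- c(vals, counts / npairs)
    gap <- strrep("*", k)
    tags <- c(tags, as.vector(t(outer(AA_ALPHABET, AA_ALPHABET,
                                      function(x, y) paste0(x, gap, y)))))
  }
  feature_block("CKSAAP", vals, tags)
}

#' Fit a position weight matrix on training fragments
#'
#' `pwm[a, p]` is the frequency of residue `a` at window position `p` over
#' the training fragments (pseudocount 0). Fit on the training fold only.
#' With `labels` supplied, one PWM per class is returned (the non-default
#' class-conditional mode).
#'
#' @param sequences character vector of equal-length fragments.
#' @param labels optional factor of per-fragment classes; if given, a named
#'   list of per-class PWMs is returned.
#' @return a `pwmatrix` (20 x L, columns summing to 1) or a list of them.
#' @export
fit_pwm <- function(sequences, labels = NULL) {
  if (length(sequences) == 0) stop("empty training set")
  if (!is.null(labels)) {
    return(lapply(split(sequences, labels), fit_pwm))
  }
  L <- nchar(sequences[1])
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)), nrow = L)
  pwm <- vapply(seq_len(L), function(p) {
    tabulate(match(mat[p, ], AA_ALPHABET), nbins = 20) / length(sequences)
  }, numeric(20))
  dimnames(pwm) <- list(AA_ALPHABET, position_labels(L))
  structure(pwm, class = c("pwmatrix", "matrix"), n = length(sequences))
}

#' Encode a fragment against a fitted position weight matrix
#'
#' Emits the positional frequency of the fragment's own residue at each of
#' the L window positions (17 dimensions).
#'
#' @param sequence fragment string.
#' @param pwm a `pwmatrix` from [fit_pwm()].
#' @return a `feature_block`.
#' @export
encode_pwm <- function(sequence, pwm) {
  chars <- seq_chars(sequence)
  check_canonical(chars)
  L <- length(chars)
  if (ncol(pwm) != L) stop("PWM width does not match fragment length")
  vals <- pwm[cbind(match(chars, AA_ALPHABET), seq_len(L))]
  feature_block("PWM", vals, position_labels(L))
}

#' Reduced 8-letter alphabet one-hot encoding
#'
#' Each residue becomes a one-hot vector over the eight physicochemical
#' groups (acid, basic, aromatic, amide, small hydroxyl, sulfur,
#' aliphatic 1, aliphatic 2), position-major (8L = 136 dimensions).
#'
#' @param sequence fragment string.
#' @return a `feature_block`.
#' @export
encode_reduced_alphabet <- function(sequence) {
  chars <- seq_chars(sequence)
  check_canonical(chars)
  gidx <- reduced_group_index()[chars]
  L <- length(chars)
  vals <- numeric(8L * L)
  vals[(seq_len(L) - 1L) * 8L + gidx] <- 1
  pos <- position_labels(L)
  tags <- as.vector(vapply(pos, function(p) paste0(names(REDUCED_GROUPS), "@", p),
                           character(8)))
  feature_block("ReducedAlphabet", vals, tags)
}

#' Windowed packing-density (amyloidogenicity) profile
#'
#' Per-residue score is the mean packing density over a centred window
#' (truncated at the fragment ends); `mode = "binary"` thresholds the
#' profile at `cutoff` (L = 17 dimensions).
#'
#' @param sequence fragment string.
#' @param scale per-residue packing-density scale
#'   (default [foldamyloid_scale()]).
#' @param window odd window width (default 5).
#' @param cutoff threshold for binary mode (default 21.4 contacts).
#' @param mode `"raw"` (default) or `"binary"`.
#' @return a `feature_block`.
#' @export
encode_foldamyloid <- function(sequence, scale = foldamyloid_scale(),
                               window = 5, cutoff = 21.4,
                               mode = c("raw", "binary")) {
  mode <- match.arg(mode)
  chars <- seq_chars(sequence)
  check_canonical(chars)
  L <- length(chars)
  raw <- scale[chars]
  half <- window %/% 2
  vals <- vapply(seq_len(L), function(i) {
    mean(raw[max(1, i - half):min(L, i + half)])
  }, numeric(1))
  if (mode == "binary") vals <- as.numeric(vals >= cutoff)
  feature_block("FoldAmyloid", vals, position_labels(L))
}

#' Binary one-hot encoding (BE)
#'
#' Each residue becomes a 20-dimensional one-hot vector over the
#' alphabetical residue order, position-major (20L = 340 dimensions).
#'
#' @param sequence fragment string.
#' @return a `feature_block`.
#' @export
encode_binary <- function(sequence) {
  chars <- seq_chars(sequence)
  check_canonical(chars)
  L <- length(chars)
  idx <- match(chars, AA_ALPHABET)
  vals <- numeric(20L * L)
  vals[(seq_len(L) - 1L) * 20L + idx] <- 1
  pos <- position_labels(L)
  tags <- as.vector(vapply(pos, function(p) paste0(AA_ALPHABET, "@", p),
                           character(20)))
  feature_block("BE", vals, tags)
}

## Normalized residue frequencies of a fragment (sums to 1).
residue_freq <- function(chars) {
  tabulate(match(chars, AA_ALPHABET), nbins = 20) / length(chars)
}

#' Parallel-correlation pseudo amino acid composition (PC-PseAAC)
#'
#' Augments the 20 residue frequencies with `lambda` sequence-order
#' correlation factors. The correlation of two residues is the mean, over
#' the three property scales, of the squared property difference; the k-th
#' factor averages it over all residue pairs k apart. Components are
#' jointly normalised so the (20 + lambda = 36)-dimensional vector sums
#' to 1.
#'
#' @param sequence fragment string.
#' @param lambda maximum sequence-order rank; default L - 1 = 16.
#' @param w weight of the correlation factors; default 0.05.
#' @param properties residues x 3 matrix (hydrophilicity, hydrophobicity,
#'   mass), z-scored; default [pseaac_properties()].
#' @return a `feature_block`.
#' @export
encode_pc_pseaac <- function(sequence, lambda = 16, w = 0.05,
                             properties = pseaac_properties()) {
  chars <- seq_chars(sequence)
  check_canonical(chars)
  L <- length(chars)
  if (lambda >= L) stop("lambda must be < fragment length")
  H <- properties[chars, , drop = FALSE]          # L x 3
  theta <- vapply(seq_len(lambda), function(k) {
    i <- seq_len(L - k)
    mean(rowMeans((H[i + k, , drop = FALSE] - H[i, , drop = FALSE])^2))
  }, numeric(1))
  f <- residue_freq(chars)
  denom <- sum(f) + w * sum(theta)
  vals <- c(f, w * theta) / denom
  tags <- c(paste0("f(", AA_ALPHABET, ")"), paste0("theta_", seq_len(lambda)))
  feature_block("PC-PseAAC", vals, tags)
}

#' Series-correlation pseudo amino acid composition (SC-PseAAC)
#'
#' Like [encode_pc_pseaac()] but with one correlation factor per property
#' and lag: the factor for lag k and property g averages the product
#' H_g(R_i) * H_g(R_(i+k)) over the sequence, giving 2*lambda factors
#' (hydrophilicity and hydrophobicity) and a (20 + 2*lambda = 52)-
#' dimensional vector summing to 1.
#'
#' @inheritParams encode_pc_pseaac
#' @param properties residues x 2 matrix (hydrophilicity, hydrophobicity),
#'   z-scored; default first two columns of [pseaac_properties()].
#' @return a `feature_block`.
#' @export
encode_sc_pseaac <- function(sequence, lambda = 16, w = 0.05,
                             properties = pseaac_properties()[, 1:2]) {
  chars <- seq_chars(sequence)
  check_canonical(chars)
  L <- length(chars)
  if (lambda >= L) stop("lambda must be < fragment length")
  G <- ncol(properties)
  H <- properties[chars, , drop = FALSE]
  tau <- numeric(G * lambda)
  tags_tau <- character(G * lambda)
  for (k in seq_len(lambda)) {
    i <- seq_len(L - k)
    for (g in seq_len(G)) {
      j <- G * (k - 1L) + g
      tau[j] <- mean(H[i, g] * H[i + k, g])
      tags_tau[j] <- paste0("tau_", k, "_", colnames(properties)[g])
    }
  }
  f <- residue_freq(chars)
  denom <- sum(f) + w * sum(tau)
  vals <- c(f, w * tau) / denom
  feature_block("SC-PseAAC", vals, c(paste0("f(", AA_ALPHABET, ")"), tags_tau))
}

## Fixed order and tags of the 19 per-residue structural channels.
STRUCT_CHANNELS <- c("asa", "ss3_H", "ss3_E", "ss3_C",
                     "ss8_G", "ss8_H", "ss8_I", "ss8_B", "ss8_E", "ss8_T",
                     "ss8_S", "ss8_C",
                     "phi", "psi", "theta", "tau", "hse_up", "hse_down", "cn")
STRUCT_TAGS <- c("ASA", "SS-Q3-H", "SS-Q3-E", "SS-Q3-C",
                 "SS-Q8-G", "SS-Q8-H", "SS-Q8-I", "SS-Q8-B", "SS-Q8-E",
                 "SS-Q8-T", "SS-Q8-S", "SS-Q8-C",
                 "phi", "psi", "theta", "tau", "HSEa-up", "HSEa-down", "CN")

#' Read a per-residue structural-feature table
#'
#' Tab-separated with columns `protein_id`, `position` and the 19 channel
#' columns `asa`, `ss3_H`, `ss3_E`, `ss3_C`, `ss8_G` .. `ss8_C`, `phi`,
#' `psi`, `theta`, `tau`, `hse_up`, `hse_down`, `cn` (secondary-structure
#' predictor output, one row per residue).
#'
#' @param path TSV path.
#' @return a data frame.
#' @export
read_structure <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", STRUCT_CHANNELS)
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("structure table lacks column(s): ", paste(missing, collapse = ", "))
  tab[need]
}

#' Encode the structural block of a fragment
#'
#' Looks up the 19 structural channels for each of the fragment's residues
#' (positions site - xi .. site + xi of its protein) and concatenates them
#' position-major in the fixed channel order (19L = 323 dimensions).
#'
#' @param protein_id,site fragment provenance (1-based central lysine).
#' @param structure data frame from [read_structure()].
#' @param L window length; default 17.
#' @return a `feature_block`.
#' @export
encode_structure <- function(protein_id, site, structure, L = 17) {
  xi <- (L - 1L) %/% 2L
  positions <- (site - xi):(site + xi)
  key <- paste(structure$protein_id, structure$position)
  rows <- match(paste(protein_id, positions), key)
  if (anyNA(rows)) {
    miss <- positions[is.na(rows)]
    stop("structure table misses ", protein_id, " position(s) ",
         paste(miss, collapse = ", "))
  }
  block <- as.matrix(structure[rows, STRUCT_CHANNELS])   # L x 19
  pos <- position_labels(L)
  tags <- as.vector(vapply(pos, function(p) paste0(STRUCT_TAGS, "@", p),
                           character(19)))
  feature_block("Structure", as.vector(t(block)), tags)
}

#' Encode a fragment with all schemes
#'
#' Concatenates the blocks in the fixed order AAindex, CKSAAP, PWM,
#' ReducedAlphabet, FoldAmyloid, BE, PC-PseAAC, SC-PseAAC, Structure
#' (2359 dimensions with all nine; 2036 without the structural block).
#'
#' @param sequence fragment string.
#' @param pwm fitted `pwmatrix` (training fold only).
#' @param protein_id,site provenance, required when `structure` is given.
#' @param structure optional structural table; `NULL` omits the block.
#' @param schemes character vector of scheme names to include.
#' @return a list with `values` (numeric vector) and `provenance`
#'   (data frame with columns `scheme`, `tag`, one row per column).
#' @export
encode_all <- function(sequence, pwm, protein_id = NULL, site = NULL,
                       structure = NULL,
                       schemes = c("AAindex", "CKSAAP", "PWM",
                                   "ReducedAlphabet", "FoldAmyloid", "BE",
                                   "PC-PseAAC", "SC-PseAAC", "Structure")) {
  blocks <- list()
  if ("AAindex" %in% schemes) blocks <- c(blocks, list(encode_aaindex(sequence)))
  if ("CKSAAP" %in% schemes) blocks <- c(blocks, list(encode_cksaap(sequence)))
  if ("PWM" %in% schemes) blocks <- c(blocks, list(encode_pwm(sequence, pwm)))
  if ("ReducedAlphabet" %in% schemes)
    blocks <- c(blocks, list(encode_reduced_alphabet(sequence)))
  if ("FoldAmyloid" %in% schemes)
    blocks <- c(blocks, list(encode_foldamyloid(sequence)))
  if ("BE" %in% schemes) blocks <- c(blocks, list(encode_binary(sequence)))
  if ("PC-PseAAC" %in% schemes) blocks <- c(blocks, list(encode_pc_pseaac(sequence)))
  if ("SC-PseAAC" %in% schemes) blocks <- c(blocks, list(encode_sc_pseaac(sequence)))
  if ("Structure" %in% schemes && !is.null(structure))
    blocks <- c(blocks, list(encode_structure(protein_id, site, structure)))
  list(values = unlist(lapply(blocks, `[[`, "values"), use.names = FALSE),
       provenance = data.frame(
         scheme = unlist(lapply(blocks, function(b) rep(b$scheme, length(b$values)))),
         tag = unlist(lapply(blocks, `[[`, "tags")),
         stringsAsFactors = FALSE))
}

#' Encode a whole dataset into a feature matrix
#'
#' @param dataset a `lys_dataset` or a fragment data frame with columns
#'   `protein_id`, `site`, `sequence`.
#' @param pwm fitted `pwmatrix`; if `NULL`, fitted on `dataset` itself
#'   (only appropriate when `dataset` is the training fold).
#' @inheritParams encode_all
#' @return a list with `X` (samples x features matrix), `provenance`
#'   (column provenance data frame) and `pwm` (the PWM used).
#' @export
encode_dataset <- function(dataset, pwm = NULL, structure = NULL,
                           schemes = c("AAindex", "CKSAAP", "PWM",
                                       "ReducedAlphabet", "FoldAmyloid", "BE",
                                       "PC-PseAAC", "SC-PseAAC", "Structure")) {
  fr <- if (inherits(dataset, "lys_dataset")) dataset$fragments else dataset
  if (is.null(pwm)) pwm <- fit_pwm(fr$sequence)
  first <- encode_all(fr$sequence[1], pwm, fr$protein_id[1], fr$site[1],
                      structure, schemes)
  X <- matrix(0, nrow = nrow(fr), ncol = length(first$values))
  X[1, ] <- first$values
  if (nrow(fr) > 1) {
    for (i in 2:nrow(fr)) {
      X[i, ] <- encode_all(fr$sequence[i], pwm, fr$protein_id[i], fr$site[i],
                           structure, schemes)$values
    }
  }
  colnames(X) <- paste0(abbreviate(first$provenance$scheme, 4), ".",
                        seq_len(ncol(X)))
  list(X = X, provenance = first$provenance, pwm = pwm)
}
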