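#' Read a multi-record FASTA file of protein sequences
#'
#' Wrapped lines are handled; record names are truncated at the first
#' whitespace.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of upper-case amino-acid sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Read a modification-site annotation table
#'
#' Tab-separated with columns `protein_id`, `position` (1-based residue
#' index of the modified lysine) and `modification` (type name).
#'
#' @param path path to a TSV file.
#' @return a data frame with the three columns above.
#' @export
read_sites <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "modification")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("site table lacks column(s): ", paste(missing, collapse = ", "))
  tab[need]
}

#' Extract lysine-centered peptide windows
#'
#' Slides a window of `2 * xi + 1` residues over each annotated lysine.
#' Sites with fewer than `xi` residues on either flank are dropped (no
#' padding), as are windows containing non-canonical letters. Annotations
#' pointing at a residue that is not lysine, or at an unknown protein, are
#' rejected with a warning.
#'
#' @param proteins named character vector, protein id to sequence.
#' @param sites annotation data frame as returned by [read_sites()].
#' @param xi flank width in residues; the default 8 gives 17-mers.
#' @return a data frame with columns `protein_id`, `site`, `sequence`,
#'   `modification` (one row per surviving annotation record).
#' @export
extract_fragments <- function(proteins, sites, xi = 8) {
  stopifnot(xi >= 1)
  n <- nrow(sites)
  keep <- logical(n)
  frag <- character(n)
  n_bad_protein <- 0L; n_not_k <- 0L; n_noncanon <- 0L
  for (i in seq_len(n)) {
    pid <- sites$protein_id[i]
    pos <- sites$position[i]
    seqi <- if (pid %in% names(proteins)) proteins[[pid]] else NA_character_
    if (is.na(seqi)) { n_bad_protein <- n_bad_protein + 1L; next }
    if (pos < 1 || pos > nchar(seqi)) { n_bad_protein <- n_bad_protein + 1L; next }
    if (substr(seqi, pos, pos) != "K") { n_not_k <- n_not_k + 1L; next }
    if (pos - xi < 1 || pos + xi > nchar(seqi)) next  # short flank: silently dropped
    w <- substr(seqi, pos - xi, pos + xi)
    if (!all(seq_chars(w) %in% AA_ALPHABET)) { n_noncanon <- n_noncanon + 1L; next }
    keep[i] <- TRUE
    frag[i] <- w
  }
  if (n_bad_protein > 0)
    warning(n_bad_protein, " record(s) rejected: unknown protein id or out-of-range position")
  if (n_not_k > 0)
    warning(n_not_k, " record(s) rejected: annotated residue is not lysine")
  if (n_noncanon > 0)
    warning(n_noncanon, " record(s) dropped: non-canonical residue in window")
  data.frame(protein_id = sites$protein_id[keep],
             site = sites$position[keep],
             sequence = frag[keep],
             modification = sites$modification[keep],
             stringsAsFactors = FALSE)
}

#' Fraction of identical positions between two equal-length sequences
#'
#' @param a,b amino-acid strings of equal length.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stop("sequences differ in length")
  mean(ca == cb)
}

#' Merge annotation records referring to the same fragment
#'
#' Records sharing (protein id, site, sequence) collapse to one record
#' whose label set is the union of the source modification names.
#'
#' @param fragments data frame from [extract_fragments()].
#' @return a data frame with columns `protein_id`, `site`, `sequence` and a
#'   list-column `labels` (sorted unique modification names), in first-seen
#'   order.
#' @export
merge_labels <- function(fragments) {
  key <- paste(fragments$protein_id, fragments$site, fragments$sequence, sep = "\r")
  first <- !duplicated(key)
  out <- fragments[first, c("protein_id", "site", "sequence")]
  rownames(out) <- NULL
  out$labels <- unname(lapply(split(fragments$modification, factor(key, levels = key[first])),
                              function(m) sort(unique(m))))
  out
}

#' Remove redundant fragments by greedy sequence-identity screening
#'
#' A greedy keep-first scan in input order: a fragment is dropped iff its
#' pairwise identity to any already-retained fragment is at least
#' `threshold`. Input order is file order, so runs are reproducible.
#'
#' @param fragments data frame with a `sequence` column (all equal length).
#' @param threshold identity fraction in (0, 1\]; default 0.40.
#' @return the retained rows of `fragments`.
#' @export
remove_redundant <- function(fragments, threshold = 0.40) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(fragments)
  if (n == 0) return(fragments)
  L <- nchar(fragments$sequence[1])
  if (any(nchar(fragments$sequence) != L)) stop("fragments differ in length")
  mat <- matrix(match(unlist(strsplit(fragments$sequence, "", fixed = TRUE)), AA_ALPHABET),
                nrow = L)
  kept <- integer(n); nk <- 0L
  retained <- matrix(0L, nrow = L, ncol = n)
  for (i in seq_len(n)) {
    v <- mat[, i]
    if (nk > 0L) {
      hits <- colSums(retained[, seq_len(nk), drop = FALSE] == v) / L
      if (any(hits >= threshold)) next
    }
    nk <- nk + 1L
    kept[nk] <- i
    retained[, nk] <- v
  }
  out <- fragments[kept[seq_len(nk)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the final single-label multi-class dataset
#'
#' Keeps only records whose full label set is a single modification type
#' belonging to a class with at least `min_count` such records. Class names
#' are ordered lexicographically and fragments carry a class factor.
#'
#' @param fragments data frame with a `labels` list-column (see
#'   [merge_labels()]); a plain `modification` column is promoted to
#'   singleton label sets.
#' @param min_count minimum surviving-class size; default 500.
#' @param single_label_only drop multi-label records (default `TRUE`).
#' @return an object of class `lys_dataset`: a list with `fragments`
#'   (columns `protein_id`, `site`, `sequence`, `class`), `classes`
#'   (lexicographic names) and `counts`.
#' @export
filter_classes <- function(fragments, min_count = 500, single_label_only = TRUE) {
  if (is.null(fragments$labels)) {
    fragments$labels <- as.list(fragments$modification)
  }
  nlab <- lengths(fragments$labels)
  if (single_label_only) fragments <- fragments[nlab == 1L, , drop = FALSE]
  lab <- vapply(fragments$labels, `[[`, character(1), 1L)
  counts <- table(lab)
  keep_classes <- sort(names(counts)[counts >= min_count])
  if (length(keep_classes) == 0) stop("no class reaches min_count = ", min_count)
  sel <- lab %in% keep_classes
  out <- fragments[sel, c("protein_id", "site", "sequence")]
  rownames(out) <- NULL
  out$class <- factor(lab[sel], levels = keep_classes)
  structure(list(fragments = out,
                 classes = keep_classes,
                 counts = as.integer(table(out$class))),
            class = "lys_dataset")
}

#' @export
print.lys_dataset <- function(x, ...) {
  cat("lys_dataset:", nrow(x$fragments), "fragments,",
      length(x$classes), "classes\n")
  print(stats::setNames(x$counts, x$classes))
  invisible(x)
}

#' Full preprocessing chain: windows, label merging, redundancy, class filter
#'
#' @inheritParams extract_fragments
#' @param identity_threshold pairwise-identity cutoff for
#'   [remove_redundant()].
#' @param min_count minimum class size for [filter_classes()].
#' @return a `lys_dataset`.
#' @export
prepare_dataset <- function(proteins, sites, xi = 8,
                            identity_threshold = 0.40, min_count = 500) {
  frags <- extract_fragments(proteins, sites, xi = xi)
  merged <- merge_labels(frags)
  nonred <- remove_redundant(merged, threshold = identity_threshold)
  filter_classes(nonred, min_count = min_count)
}

#' Write a prepared dataset as TSV
#'
#' Columns: protein_id, position (1-based central lysine), sequence,
#' class_index (1-based, lexicographic class order), class.
#'
#' @param dataset a `lys_dataset`.
#' @param path output file.
#' @export
write_dataset <- function(dataset, path) {
  fr <- dataset$fragments
  out <- data.frame(protein_id = fr$protein_id, position = fr$site,
                    sequence = fr$sequence,
                    class_index = as.integer(fr$class),
                    class = as.character(fr$class))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path TSV path.
#' @return a `lys_dataset`.
#' @export
read_dataset <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  classes <- sort(unique(tab$class))
  out <- data.frame(protein_id = tab$protein_id, site = tab$position,
                    sequence = tab$sequence,
                    class = factor(tab$class, levels = classes),
                    stringsAsFactors = FALSE)
  structure(list(fragments = out, classes = classes,
                 counts = as.integer(table(out$class))),
            class = "lys_dataset")
}
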