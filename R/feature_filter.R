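#' Pearson product-moment correlation of two vectors
#'
#' Thin validated wrapper used by the feature screen.
#'
#' @param x,y numeric vectors of equal length (at least 2), non-constant.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)
}

#' Fit a Pearson-correlation feature-selection mask
#'
#' Zero-variance columns are removed first. In the default
#' `"feature-label"` mode a column is dropped when the absolute correlation
#' between the column and the numeric class label exceeds `threshold`. In
#' `"feature-feature"` mode a greedy scan in column order drops a column
#' when its absolute correlation with any already-retained column exceeds
#' `threshold`. Fit the mask on the training fold only and apply it
#' unchanged to validation/test folds.
#'
#' @param X samples x features numeric matrix (training fold).
#' @param labels class factor (or integer vector) for `X`'s rows; ignored
#'   in feature-feature mode.
#' @param mode `"feature-label"` (default) or `"feature-feature"`.
#' @param threshold absolute-correlation bound; default 0.5.
#' @param label_encoding how classes enter the correlation:
#'   `"index"` (default, integer class indices) or `"one-vs-rest"`
#'   (per-class binary indicators; a column is screened on its maximum
#'   absolute correlation over classes).
#' @param provenance optional column-provenance data frame, subset and
#'   carried along.
#' @return a `pcc_mask`: list with `kept` (strictly increasing column
#'   indices), `mode`, `threshold`, `p` (original width) and `provenance`.
#' @export
fit_pcc_filter <- function(X, labels = NULL,
                           mode = c("feature-label", "feature-feature"),
                           threshold = 0.5,
                           label_encoding = c("index", "one-vs-rest"),
                           provenance = NULL) {
  mode <- match.arg(mode)
  label_encoding <- match.arg(label_encoding)
  p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  nonconst <- which(sds > 0)
  if (mode == "feature-label") {
    if (is.null(labels)) stop("labels required in feature-label mode")
    if (label_encoding == "index") {
      y <- as.numeric(as.integer(factor(labels)))
      r <- abs(suppressWarnings(stats::cor(X[, nonconst, drop = FALSE], y)))[, 1]
    } else {
      f <- factor(labels)
      Y <- vapply(levels(f), function(l) as.numeric(f == l),
                  numeric(length(labels)))
      r <- apply(abs(suppressWarnings(
        stats::cor(X[, nonconst, drop = FALSE], Y))), 1, max)
    }
    kept <- nonconst[r <= threshold]
  } else {
    Z <- scale(X[, nonconst, drop = FALSE])
    n <- nrow(Z)
    kept_local <- integer(0)
    for (j in seq_along(nonconst)) {
      if (length(kept_local) > 0) {
        r <- abs(crossprod(Z[, kept_local, drop = FALSE], Z[, j])) / (n - 1)
        if (any(r > threshold)) next
      }
      kept_local <- c(kept_local, j)
    }
    kept <- nonconst[kept_local]
  }
  if (length(kept) == 0) stop("all columns dropped by the PCC filter")
  structure(list(kept = as.integer(kept), mode = mode, threshold = threshold,
                 p = p,
                 provenance = if (!is.null(provenance))
                   provenance[kept, , drop = FALSE] else NULL),
            class = "pcc_mask")
}

#' Apply a fitted selection mask to a feature matrix
#'
#' @param mask a `pcc_mask` from [fit_pcc_filter()].
#' @param X samples x features matrix with the width the mask was fit on.
#' @return the reduced matrix.
#' @export
apply_pcc_filter <- function(mask, X) {
  if (ncol(X) != mask$p) stop("matrix width does not match the fitted mask")
  X[, mask$kept, drop = FALSE]
}

#' Serialize / read a selection mask as JSON
#'
#' @param mask a `pcc_mask`.
#' @param path JSON file path.
#' @export
write_pcc_mask <- function(mask, path) {
  obj <- list(mode = mask$mode, threshold = mask$threshold, p = mask$p,
              kept = mask$kept)
  if (!is.null(mask$provenance)) {
    obj$scheme_summary <- as.list(table(mask$provenance$scheme))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pcc_mask
#' @return `read_pcc_mask()` returns the `pcc_mask`.
#' @export
read_pcc_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kept = as.integer(obj$kept), mode = obj$mode,
                 threshold = obj$threshold, p = as.integer(obj$p),
                 provenance = NULL),
            class = "pcc_mask")
}
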