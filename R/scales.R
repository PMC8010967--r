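#' @keywords internal
"_PACKAGE"

## Canonical amino-acid alphabet, alphabetical one-letter order.
## All encoders index residues in this order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default physicochemical property table for the AAindex encoder
#'
#' Fourteen published per-residue scales used by [encode_aaindex()]:
#' hydrophobicity (Kyte-Doolittle), hydrophilicity (Hopp-Woods), residue
#' mass, isoelectric point, side-chain volume, polarity (Grantham),
#' polarizability, maximum solvent accessibility, chain flexibility,
#' net charge index, pK of the alpha-carboxyl and alpha-amino groups,
#' fraction buried, and molar refractivity. Any 20-row numeric matrix with
#' the canonical residues as row names can be substituted.
#'
#' @param zscore if `TRUE` (default) each property is centred and scaled
#'   across the 20 residues (population standard deviation), the form the
#'   encoder expects.
#' @return a 20 x 14 numeric matrix, rows named by residue, columns by
#'   property.
#' @export
aaindex_properties <- function(zscore = TRUE) {
  tab <- cbind(
    hydrophobicity = c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
                       1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3),
    hydrophilicity = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
                       -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3),
    mass = c(71.08, 103.14, 115.09, 129.12, 147.18, 57.05, 137.14, 113.16,
             128.17, 113.16, 131.19, 114.10, 97.12, 128.13, 156.19, 87.08,
             101.10, 99.13, 186.21, 163.18),
    isoelectric_point = c(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74,
                          5.98, 5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.60, 5.96,
                          5.89, 5.66),
    volume = c(88.6, 108.5, 111.1, 138.4, 189.9, 60.1, 153.2, 166.7, 168.6,
               166.7, 162.9, 114.1, 112.7, 143.8, 173.4, 89.0, 116.1, 140.0,
               227.8, 193.6),
    polarity = c(8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
                 5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2),
    polarizability = c(0.046, 0.128, 0.105, 0.151, 0.290, 0.000, 0.230, 0.186,
                       0.219, 0.186, 0.221, 0.134, 0.131, 0.180, 0.291, 0.062,
                       0.108, 0.140, 0.409, 0.298),
    solvent_accessibility = c(129, 167, 193, 223, 240, 104, 224, 197, 236, 201,
                              224, 195, 159, 225, 274, 155, 172, 174, 285, 263),
    flexibility = c(0.357, 0.346, 0.511, 0.497, 0.314, 0.544, 0.323, 0.462,
                    0.466, 0.365, 0.295, 0.463, 0.509, 0.493, 0.529, 0.507,
                    0.444, 0.386, 0.305, 0.420),
    net_charge_index = c(0.00719, -0.03661, -0.02382, 0.00680, 0.03755, 0.17905,
                         -0.01069, 0.02163, 0.01771, 0.05167, 0.00268, 0.00539,
                         0.23953, 0.04921, 0.04359, 0.00463, 0.00335, 0.05700,
                         0.03798, 0.02360),
    pk_cooh = c(2.34, 1.96, 1.88, 2.19, 1.83, 2.34, 1.82, 2.36, 2.18, 2.36,
                2.28, 2.02, 1.99, 2.17, 2.17, 2.21, 2.09, 2.32, 2.83, 2.20),
    pk_nh2 = c(9.69, 10.28, 9.60, 9.67, 9.13, 9.60, 9.17, 9.60, 8.95, 9.60,
               9.21, 8.80, 10.60, 9.13, 9.04, 9.15, 9.10, 9.62, 9.39, 9.11),
    buriedness = c(0.38, 0.50, 0.135, 0.18, 0.48, 0.36, 0.17, 0.60, 0.03, 0.45,
                   0.40, 0.12, 0.18, 0.07, 0.01, 0.22, 0.23, 0.54, 0.27, 0.15),
    refractivity = c(4.34, 35.77, 13.28, 17.56, 29.40, 0.00, 21.81, 19.06,
                     21.29, 18.78, 21.64, 13.28, 10.93, 17.26, 26.66, 6.35,
                     11.01, 13.92, 42.53, 31.53)
  )
  rownames(tab) <- AA_ALPHABET
  if (zscore) tab <- apply(tab, 2, zscore20)
  tab
}

#' Property table for the pseudo amino acid composition encoders
#'
#' The three classical PseAAC scales: hydrophilicity (Hopp-Woods),
#' hydrophobicity, and side-chain mass. The parallel-correlation encoder
#' uses all three; the series-correlation encoder uses the first two.
#'
#' @param zscore if `TRUE` (default) normalise each scale across the 20
#'   residues using the population standard deviation, the standard PseAAC
#'   convention.
#' @return a 20 x 3 numeric matrix, rows named by residue.
#' @export
pseaac_properties <- function(zscore = TRUE) {
  tab <- cbind(
    hydrophilicity = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
                       -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3),
    hydrophobicity = c(0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38, -1.50,
                       1.06, 0.64, -0.78, 0.12, -0.85, -2.53, -0.18, -0.05,
                       1.08, 0.81, 0.26),
    mass = c(15.0, 47.0, 59.0, 73.0, 91.0, 1.0, 82.0, 57.0, 73.0, 57.0,
             75.0, 58.0, 42.0, 72.0, 101.0, 31.0, 45.0, 43.0, 130.0, 107.0)
  )
  rownames(tab) <- AA_ALPHABET
  if (zscore) tab <- apply(tab, 2, zscore20)
  tab
}

#' Packing-density scale for the amyloidogenicity encoder
#'
#' Per-residue expected packing density (expected number of contacts within
#' 8 angstroms); hydrophobic beta-prone residues score high, glycine,
#' proline and charged residues low. Averaged over a sliding window this
#' profiles amyloidogenic regions; [encode_foldamyloid()] thresholds it at
#' 21.4 contacts in binary mode.
#'
#' @return a named numeric vector over the 20 canonical residues.
#' @export
foldamyloid_scale <- function() {
  stats::setNames(
    c(20.1, 22.0, 17.4, 17.7, 22.4, 18.2, 20.4, 22.6, 16.9, 22.1,
      21.9, 17.9, 17.5, 18.2, 18.3, 18.9, 19.4, 22.5, 22.1, 21.6),
    AA_ALPHABET)
}

## Population (n = 20) z-score used for residue property scales.
zscore20 <- function(x) {
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  (x - mu) / sdev
}

## Reduced 8-letter alphabet: physicochemical residue groups.
REDUCED_GROUPS <- list(
  acid = c("D", "E"),
  basic = c("H", "K", "R"),
  aromatic = c("F", "W", "Y"),
  amide = c("N", "Q"),
  hydroxyl = c("S", "T"),
  sulfur = c("C", "M"),
  aliphatic1 = c("A", "G", "P"),
  aliphatic2 = c("I", "L", "V")
)

reduced_group_index <- function() {
  idx <- integer(20)
  names(idx) <- AA_ALPHABET
  for (g in seq_along(REDUCED_GROUPS)) idx[REDUCED_GROUPS[[g]]] <- g
  idx
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

check_canonical <- function(chars) {
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0)
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
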