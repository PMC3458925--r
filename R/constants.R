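# Residue alphabets, category sets and physico-chemical reference tables.
# All sets the underlying study leaves implicit are gathered here so they can
# be inspected or overridden in one place.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes, alphabetically ordered.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Tolerated ambiguity codes
#'
#' Non-standard residue codes accepted by the tolerant FASTA reader. They are
#' skipped in feature numerators but count toward sequence length.
#' @export
AA_AMBIGUITY <- c("X", "B", "Z", "U", "J", "O")

#' Residue category sets
#'
#' Membership sets behind the category features (small, tiny, aromatic,
#' aliphatic, hydrophobic, polar, charge and side-chain hydrogen-bond
#' capability). Small, tiny and aromatic follow the published definitions;
#' the remaining sets are the package's documented choices and can be
#' overridden via the `sets` argument of [category_features()].
#'
#' @return Named list of character vectors of one-letter residue codes.
#' @export
residue_sets <- function() {
  list(
    small       = c("T", "D"),
    tiny        = c("G", "A", "S", "P"),
    aromatic    = c("F", "H", "Y", "W"),
    aliphatic   = c("A", "I", "L", "V"),
    hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W"),
    polar       = c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "Y"),
    positive    = c("K", "R"),
    negative    = c("D", "E"),
    hbond       = c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y")
  )
}

# Reference constant tables used by the feature calculators.

# Kyte-Doolittle hydropathy index (J Mol Biol 1982).
KYTE_DOOLITTLE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Dipeptide instability weight values (DIWV) of Guruprasad et al. (1990),
# as used by the ProtParam instability index. Rows: first residue of the
# dipeptide, columns: second residue.
DIWV_TABLE <- matrix(c(
    1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
    1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
    1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
    1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
    -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
    1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
    1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
    13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
    1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
    20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
    1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
    1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
    1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
    1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
    1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
    -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
    24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))

# Bjellqvist pKa values (as popularized by the ExPASy Compute pI tool).
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)

# Isoelectric points of the free amino acids (Lehninger), used for the
# residue-averaged pI feature.
RESIDUE_PI <- c(
  A = 6.00, C = 5.07, D = 2.77, E = 3.22, F = 5.48, G = 5.97, H = 7.59,
  I = 6.02, K = 9.74, L = 5.98, M = 5.74, N = 5.41, P = 6.30, Q = 5.65,
  R = 10.76, S = 5.68, T = 5.60, V = 5.96, W = 5.89, Y = 5.66)

# Per-residue maximum solvent-accessible surface area (A^2). Theoretical
# maxima of Tien et al. (2013); the exact max-ASA scale is configurable in
# category_features() because published scales differ by a few percent.
MAX_ASA_DEFAULT <- c(
  A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224, I = 197,
  K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225, R = 274, S = 155,
  T = 172, V = 174, W = 285, Y = 263)
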