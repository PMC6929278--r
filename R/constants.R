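#' @title Amino-acid alphabet and physicochemical constants
#' @name hexablock-constants
#' @description Internal constants: the 20-letter amino-acid alphabet in the
#'   fixed order used by every matrix in the package, three-letter code
#'   mappings, and the raw six-property physicochemical table.
NULL

## Fixed alphabet order; all L x 20 and 20 x 20 matrices use this column order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

## Fallbacks for ambiguity/non-standard codes (strict mode rejects instead).
AA_NONSTANDARD <- c(B = "N", Z = "Q", U = "C", O = "K")

PHYSCHEM_PROPERTIES <- c("H", "VSC", "P1", "P2", "SASA", "NCISC")

## Raw per-type values of hydrophobicity (H), side-chain volume (VSC),
## polarity (P1), polarizability (P2), solvent-accessible surface area (SASA)
## and net charge index of side chains (NCISC).
PHYSCHEM_RAW <- matrix(c(
  #     H    VSC    P1     P2    SASA     NCISC
   0.62,  27.5,  8.1, 0.046, 1.181,  0.007187,  # A
   0.29,  44.6,  5.5, 0.128, 1.461, -0.036610,  # C
  -0.90,  40.0, 13.0, 0.105, 1.587, -0.023820,  # D
  -0.74,  62.0, 12.3, 0.151, 1.862,  0.006802,  # E
   1.19, 115.5,  5.2, 0.290, 2.228,  0.037552,  # F
   0.48,   0.0,  9.0, 0.000, 0.881,  0.179052,  # G
  -0.40,  79.0, 10.4, 0.230, 2.025, -0.010690,  # H
   1.38,  93.5,  5.2, 0.186, 1.810,  0.021631,  # I
  -1.50, 100.0, 11.3, 0.219, 2.258,  0.017708,  # K
   1.06,  93.5,  4.9, 0.186, 1.931,  0.051672,  # L
   0.64,  94.1,  5.7, 0.221, 2.034,  0.002683,  # M
  -0.78,  58.7, 11.6, 0.134, 1.655,  0.005392,  # N
   0.12,  41.9,  8.0, 0.131, 1.468,  0.239531,  # P
  -0.85,  80.7, 10.5, 0.180, 1.932,  0.049211,  # Q
  -2.53, 105.0, 10.5, 0.291, 2.560,  0.043587,  # R
  -0.18,  29.3,  9.2, 0.062, 1.298,  0.004627,  # S
  -0.05,  51.3,  8.6, 0.108, 1.525,  0.003352,  # T
   1.08,  71.5,  5.9, 0.140, 1.645,  0.057004,  # V
   0.81, 145.5,  5.4, 0.409, 2.663,  0.037977,  # W
   0.26, 117.3,  6.2, 0.298, 2.368,  0.023599), # Y
  nrow = 20, ncol = 6, byrow = TRUE,
  dimnames = list(AA_ALPHABET, PHYSCHEM_PROPERTIES))

#' Raw physicochemical property table
#'
#' Returns the 20 x 6 table of raw physicochemical property values
#' (hydrophobicity, side-chain volume, polarity, polarizability,
#' solvent-accessible surface area, net charge index of side chains) for the
#' 20 standard amino acids, rows in the package's fixed alphabet order.
#'
#' @return A 20 x 6 numeric matrix with amino-acid rownames and property
#'   colnames.
#' @export
#' @examples
#' physchem_table()["A", "H"]
physchem_table <- function() PHYSCHEM_RAW

#' Dayhoff-style substitution matrix
#'
#' Returns a 20 x 20 amino-acid substitution matrix in the package alphabet
#' order, used to project per-position amino-acid frequencies into
#' log-odds-style profile scores. The default is the classic PAM250 log-odds
#' matrix (the common "Dayhoff matrix" dialect), taken from Biostrings'
#' packaged copy and reordered.
#'
#' @return A 20 x 20 numeric matrix, rows and columns named by the one-letter
#'   alphabet in the fixed package order.
#' @export
dayhoff_matrix <- function() {
  env <- new.env()
  utils::data("PAM250", package = "Biostrings", envir = env)
  m <- env$PAM250[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "double"
  m
}

## Map a vector of one-letter codes to row indices of the alphabet.
## strict: error on non-standard codes instead of remapping.
aa_index <- function(aa, strict = FALSE) {
  aa <- toupper(aa)
  idx <- match(aa, AA_ALPHABET)
  bad <- which(is.na(idx))
  if (length(bad)) {
    if (strict)
      stop("non-standard amino-acid code(s): ",
           paste(unique(aa[bad]), collapse = ", "))
    mapped <- AA_NONSTANDARD[aa[bad]]
    idx[bad] <- match(mapped, AA_ALPHABET)  # X and others stay NA
  }
  idx
}
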