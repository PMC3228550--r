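# Built-in residue-level constant tables.
# All tables are keyed by one-letter amino-acid code in the fixed order below.

#: canonical order used for composition vectors and PSSM columns (PSI-BLAST order)
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3_TO_1 <- structure(names(AA3), names = unname(AA3))

#' BLOSUM62 diagonal (self-substitution scores)
#'
#' The diagonal elements \eqn{B_{rr}} of the BLOSUM62 substitution matrix,
#' used as the conservation baseline against PSSM scores: a position whose
#' profile score for its own residue type falls below \eqn{B_{rr}} is
#' considered less conserved than a self-substitution and receives a positive
#' conservation score.
#'
#' @format Named integer vector over the 20 standard one-letter codes.
#' @export
blosum62_diagonal <- c(A = 4L, R = 5L, N = 6L, D = 6L, C = 9L,
                       Q = 5L, E = 5L, G = 6L, H = 8L, I = 4L,
                       L = 4L, K = 5L, M = 5L, F = 6L, P = 7L,
                       S = 4L, T = 5L, W = 11L, Y = 7L, V = 4L)

#' Maximal (fully exposed) accessible surface areas
#'
#' Reference accessible surface areas in square Angstroms of residue X in an
#' extended Gly-X-Gly tripeptide, used as the denominator when converting
#' absolute SASA to relative accessible surface area (RASA). The shipped
#' values are the theoretical maxima of Tien et al. (2013); any function that
#' consumes the table accepts an override, since published RASA values vary
#' slightly with the reference chosen.
#'
#' @format Named numeric vector (Angstrom^2) over the 20 one-letter codes.
#' @export
max_asa_gxg <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
                 Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
                 L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
                 S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Van der Waals radii (Angstrom) by element symbol; fixed built-in table so
# SASA is deterministic across platforms. Unknown heavy elements fall back to
# the carbon radius.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
               P = 1.80, H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70
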