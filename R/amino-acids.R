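#' Canonical amino-acid alphabet and residue property tables
#'
#' One-letter codes for the 20 canonical amino acids, plus the residue-level
#' property scales used by the sequence feature set: Kyte-Doolittle
#' hydropathy, net side-chain charge at pH 7, and residue volume
#' (Zamyatnin, cubic Angstroms). Histidine is treated as neutral at pH 7
#' (its imidazole pKa ~6 leaves it mostly deprotonated); this convention is
#' deliberate and documented rather than using a fractional charge.
#'
#' @format `aa_alphabet` is a character vector of length 20 (alphabetical).
#'   `aa_hydropathy`, `aa_charge` and `aa_volume` are named numeric vectors
#'   over that alphabet.
#' @name amino_acid_tables
NULL

#' @rdname amino_acid_tables
#' @export
aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname amino_acid_tables
#' @export
aa_hydropathy <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' @rdname amino_acid_tables
#' @export
aa_charge <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0,
  G = 0, H = 0, I = 0, K = 1, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 1,
  S = 0, T = 0, V = 0, W = 0, Y = 0
)

#' @rdname amino_acid_tables
#' @export
aa_volume <- c(
  A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
  G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
  M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
  S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6
)

# BLOSUM62 is loaded lazily from Biostrings and cached for the session.
.blosum_env <- new.env(parent = emptyenv())

#' Substitution-matrix score for an amino-acid exchange
#'
#' Looks up the BLOSUM62 score for replacing `ref` with `alt`. Vectorized.
#'
#' @param ref,alt one-letter amino-acid codes.
#' @return numeric vector of BLOSUM62 scores.
#' @export
blosum62_score <- function(ref, alt) {
  if (is.null(.blosum_env$BLOSUM62)) {
    utils::data("BLOSUM62", package = "Biostrings", envir = .blosum_env)
  }
  m <- .blosum_env$BLOSUM62
  stopifnot(all(ref %in% rownames(m)), all(alt %in% colnames(m)))
  m[cbind(ref, alt)]
}
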