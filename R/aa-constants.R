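#' Amino-acid alphabet and reference tables
#'
#' The package works over the fixed 20-letter amino-acid alphabet
#' `ACDEFGHIKLMNPQRSTVWY` (alphabetical by one-letter code). `'X'` marks
#' unknown or masked residues and is excluded from all statistics.
#'
#' @format `AA_ALPHABET` is a character vector of length 20.
#' @export
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# Three-letter -> one-letter residue codes; MSE (selenomethionine) maps to M,
# everything else unknown maps to X at the call site.
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
  MSE = "M"
)

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 integer log-odds matrix (half-bit units), restricted
#' to the 20 canonical amino acids, used as the reference for substitution
#' plausibility in [blosum_score()] and [confusion_logodds()].
#'
#' @return A 20 x 20 integer matrix with dimnames `AA_ALPHABET`.
#' @export
blosum62 <- function() {
  txt <- "
 4  0 -2 -1 -2  0 -2 -1 -1 -1 -1 -2 -1 -1 -1  1  0  0 -3 -2
 0  9 -3 -4 -2 -3 -3 -1 -3 -1 -1 -3 -3 -3 -3 -1 -1 -1 -2 -2
-2 -3  6  2 -3 -1 -1 -3 -1 -4 -3  1 -1  0 -2  0 -1 -3 -4 -3
-1 -4  2  5 -3 -2  0 -3  1 -3 -2  0 -1  2  0  0 -1 -2 -3 -2
-2 -2 -3 -3  6 -3 -1  0 -3  0  0 -3 -4 -3 -3 -2 -2 -1  1  3
 0 -3 -1 -2 -3  6 -2 -4 -2 -4 -3  0 -2 -2 -2  0 -2 -3 -2 -3
-2 -3 -1  0 -1 -2  8 -3 -1 -3 -2  1 -2  0  0 -1 -2 -3 -2  2
-1 -1 -3 -3  0 -4 -3  4 -3  2  1 -3 -3 -3 -3 -2 -1  3 -3 -1
-1 -3 -1  1 -3 -2 -1 -3  5 -2 -1  0 -1  1  2  0 -1 -2 -3 -2
-1 -1 -4 -3  0 -4 -3  2 -2  4  2 -3 -3 -2 -2 -2 -1  1 -2 -1
-1 -1 -3 -2  0 -3 -2  1 -1  2  5 -2 -2  0 -1 -1 -1  1 -1 -1
-2 -3  1  0 -3  0  1 -3  0 -3 -2  6 -2  0  0  1  0 -3 -4 -2
-1 -3 -1 -1 -4 -2 -2 -3 -1 -3 -2 -2  7 -1 -2 -1 -1 -2 -4 -3
-1 -3  0  2 -3 -2  0 -3  1 -2  0  0 -1  5  1  0 -1 -2 -2 -1
-1 -3 -2  0 -3 -2  0 -3  2 -2 -1  0 -2  1  5 -1 -1 -3 -3 -2
 1 -1  0  0 -2  0 -1 -2  0 -2 -1  1 -1  0 -1  4  1 -2 -3 -2
 0 -1 -1 -1 -2 -2 -2 -1 -1 -1 -1  0 -1 -1 -1  1  5  0 -2 -2
 0 -1 -3 -2 -1 -3 -3  3 -2  1  1 -3 -2 -2 -3 -2  0  4 -3 -1
-3 -2 -4 -3  1 -2 -2 -3 -3 -2 -1 -4 -4 -2 -3 -3 -2 -3 11  2
-2 -2 -3 -2  3 -3  2 -1 -2 -1 -1 -2 -3 -1 -2 -2 -2 -1  2  7"
  m <- matrix(scan(text = txt, quiet = TRUE), nrow = 20, byrow = TRUE)
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  storage.mode(m) <- "integer"
  m
}

#' Maximum allowed solvent accessibility (theoretical)
#'
#' Theoretical maximum accessible surface area per residue type (Tien et al.
#' 2013, Angstrom^2), used to normalize per-residue SASA into relative
#' solvent accessibility (RSA).
#'
#' @return Named numeric vector over `AA_ALPHABET`.
#' @export
max_asa_table <- function() {
  c(A = 129, C = 167, D = 193, E = 223, F = 240,
    G = 104, H = 224, I = 197, K = 236, L = 201,
    M = 224, N = 195, P = 159, Q = 225, R = 274,
    S = 155, T = 172, V = 174, W = 285, Y = 263)
}

#' Hydrophobicity classes
#'
#' Two-way residue classification used for hydrophobicity-conservation
#' scoring: hydrophobic = Ile, Leu, Met, Phe, Cys, Trp, Pro, Val, Ala, Gly;
#' hydrophilic = the remaining ten types.
#'
#' @return Named character vector mapping one-letter codes to
#'   `"hydrophobic"` or `"hydrophilic"`.
#' @export
hydrophobicity_classes <- function() {
  phobic <- c("I","L","M","F","C","W","P","V","A","G")
  cls <- ifelse(AA_ALPHABET %in% phobic, "hydrophobic", "hydrophilic")
  names(cls) <- AA_ALPHABET
  cls
}

# Van der Waals radii (A) used by the Shrake-Rupley SASA; keyed by atom role.
ATOM_RADII <- c(N = 1.65, CA = 1.87, C = 1.76, O = 1.40, CB = 1.87)

seq_to_idx <- function(seq) {
  # one-letter string or character vector -> integer indices into AA_ALPHABET,
  # NA for 'X'/unknown
  if (length(seq) == 1L && nchar(seq[1L]) > 1L) seq <- strsplit(seq, "")[[1L]]
  match(seq, AA_ALPHABET)
}

idx_to_seq <- function(idx) {
  out <- rep("X", length(idx))
  ok <- !is.na(idx)
  out[ok] <- AA_ALPHABET[idx[ok]]
  paste(out, collapse = "")
}
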