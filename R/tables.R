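# Internal lookup tables shared across modules.

# Kyte-Doolittle hydropathy values for the 20 standard amino acids.
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

STOP_CODONS <- c("TAA", "TAG", "TGA")
SD_CONSENSUS <- "AGGAGG"

.nt_alphabet <- c("A", "C", "G", "T", "N")

# standard genetic code, keyed by codon (from Biostrings)
genetic_code <- function() Biostrings::GENETIC_CODE

all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  paste0(rep(nt, each = 16L), rep(rep(nt, each = 4L), 4L), rep(nt, 16L))
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

# codons (excluding stops) per amino acid
codons_by_aa <- function() {
  gc <- genetic_code()
  gc <- gc[!names(gc) %in% STOP_CODONS]
  split(names(gc), unname(gc))
}

# EDNAFULL-equivalent nucleotide scoring used for alignment and dot plots
nt_submatrix <- function(match = 5, mismatch = -4) {
  nt <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(nt, nt))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

aa_submatrix <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# map sequence characters to 0-based integer codes over a matrix alphabet
encode_seq <- function(x, alphabet) {
  idx <- match(chars(x), alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("invalid character '", chars(x)[bad], "' at position ", bad,
         " for alphabet {", paste(alphabet, collapse = ""), "}")
  }
  idx - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
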