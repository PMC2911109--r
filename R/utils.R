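# Internal helpers: alphabet checks, reverse complement, coordinate conversion.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorized over a character vector of DNA sequences (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate that a sequence uses only A/C/G/T/N; returns position of first
# offending character or 0L if clean.
first_bad_residue <- function(seq) {
  m <- regexpr("[^ACGTN]", seq)
  as.integer(m[1])
}

# file coordinates (1-based inclusive) -> internal (0-based half-open)
coords_to_internal <- function(start1, end1) {
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

# internal (0-based half-open) -> file coordinates (1-based inclusive)
coords_to_file <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

# substring by 0-based half-open interval
subseq0 <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

# all k-mer windows of a sequence (offset 1), in order; empty when L < k
kmer_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
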