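# Small shared helpers. Coordinates everywhere are 0-based half-open on the
# plus strand unless a function documents otherwise.

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  is.character(x) & !is.na(x) & nzchar(x) & grepl(pat, x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement; input and output are plain uppercase
#' character vectors.
#'
#' @param x Character vector of DNA sequences (A, C, G, T, N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Draw random DNA sequences
#'
#' @param n Number of sequences.
#' @param width Length of each sequence in nucleotides.
#' @return Character vector of `n` random sequences over A/C/G/T, drawn from
#'   the current RNG state.
#' @export
random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}

# Nearest-integer rounding with .5 always rounded away from zero, so that a
# reported copy number of 8.5 rounds to 9 regardless of parity.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Rotate a circular sequence so that it starts at `at` (1-based).
.rotate_seq <- function(seq, at) {
  n <- nchar(seq)
  if (at == 1) return(seq)
  paste0(substr(seq, at, n), substr(seq, 1, at - 1))
}

# Locate `anchor` in the circular sequence `seq` (plus strand only); returns
# the 1-based start or NA. Searches the doubled string so matches crossing
# the linearization point are found.
.find_circular <- function(seq, anchor) {
  n <- nchar(seq)
  doubled <- paste0(seq, substr(seq, 1, min(n, nchar(anchor) - 1)))
  pos <- regexpr(anchor, doubled, fixed = TRUE)[1]
  if (pos < 1 || pos > n) NA_integer_ else pos
}
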