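# Shared low-level helpers.

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` strings.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a sequence string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# collapse a character matrix (reads in rows) back to strings
collapse_rows <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# Phred+33 encoding
qual_to_int <- function(q) lapply(q, function(s) utf8ToInt(s) - 33L)
int_to_qual <- function(q) vapply(q, function(v) intToUtf8(v + 33L), character(1))

# deterministic seed derivation for sub-stages, kept below 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1103L + stage * 7919L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
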