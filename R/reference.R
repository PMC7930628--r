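# Circular mitochondrial reference model and locus classification.

#' Construct a circular mitochondrial reference
#'
#' The human mitochondrial genome is circular: position arithmetic wraps at
#' the origin, and read mapping uses an elongated copy of the sequence (the
#' first `elongation_length` bases appended at the end) so reads spanning
#' the origin align contiguously.
#'
#' @param sequence single upper-case nucleotide string over `{A,C,G,T,N}`.
#' @param name sequence name (default `"MT"`).
#' @param elongation_length bases of the 5' end appended for mapping
#'   (default 500).
#' @return an object of class `mt_reference` with fields `name`, `sequence`,
#'   `length` and `elongation_length`.
#' @export
mt_reference <- function(sequence, name = "MT", elongation_length = 500L) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) abort("reference sequence is empty")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0) {
    abort(sprintf("illegal character '%s' in reference at position %d",
                  substr(sequence, bad, bad), bad))
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         elongation_length = as.integer(elongation_length)),
    class = "mt_reference")
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf("<mt_reference> %s: %d bp circular (elongation %d bp)\n",
              x$name, x$length, x$elongation_length))
  invisible(x)
}

#' Read a single-record FASTA reference
#'
#' Accepts any line wrapping on input; rejects multi-record files and
#' sequences containing characters outside `{A,C,G,T,N}`.
#'
#' @param path FASTA file with exactly one record.
#' @inheritParams mt_reference
#' @return an [mt_reference()] object.
#' @export
read_reference <- function(path, elongation_length = 500L) {
  if (!file.exists(path)) abort(sprintf("reference file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1) {
    abort(sprintf("expected a single-record FASTA, found %d records in %s",
                  length(ss), path))
  }
  nm <- sub("\\s.*$", "", names(ss)[1])
  mt_reference(as.character(ss[[1]]), name = nm,
               elongation_length = elongation_length)
}

#' Write a reference (or any named sequence) as 70-column FASTA
#'
#' @param sequence character string or `mt_reference`.
#' @param path output path.
#' @param name header to use when `sequence` is a plain string.
#' @export
write_fasta <- function(sequence, path, name = "sequence") {
  if (inherits(sequence, "mt_reference")) {
    name <- sequence$name
    sequence <- sequence$sequence
  }
  ss <- Biostrings::DNAStringSet(setNames(sequence, name))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' The packaged synthetic mitochondrial reference
#'
#' A 16,569 bp synthetic stand-in for an rCRS-like mitochondrial genome,
#' with the `N` placeholder at position 3107, shipped so no download is
#' ever required. A user-supplied rCRS FASTA is accepted transparently by
#' [read_reference()].
#'
#' @inheritParams mt_reference
#' @return an [mt_reference()] object.
#' @export
synthetic_reference <- function(elongation_length = 500L) {
  read_reference(
    system.file("extdata", "synthetic_mt_genome.fasta", package = "paleomt"),
    elongation_length = elongation_length)
}

#' Wrap a coordinate onto the circle
#'
#' 1-based: `wrap_position(ref, length + k)` equals `k`.
#'
#' @param ref an [mt_reference()] (or integer genome length).
#' @param position integer vector of 1-based coordinates (any integer >= 1).
#' @return integer vector in `1..length`.
#' @export
wrap_position <- function(ref, position) {
  L <- if (inherits(ref, "mt_reference")) ref$length else as.integer(ref)
  ((as.integer(position) - 1L) %% L) + 1L
}

#' Elongated sequence used for circular mapping
#'
#' The reference followed by its first `elongation_length` bases.
#'
#' @param ref an [mt_reference()].
#' @return character string of length `length + elongation_length`.
#' @export
elongate <- function(ref) {
  paste0(ref$sequence, substr(ref$sequence, 1L, ref$elongation_length))
}

# circular substring: 1-based start, may run past the origin
circular_substr <- function(ref, start, len) {
  dbl <- paste0(ref$sequence, ref$sequence)
  start <- wrap_position(ref, start)
  substring(dbl, start, start + len - 1L)
}

#' Locus map over the mitochondrial genome
#'
#' A partition of the circle into named loci (protein-coding genes, rRNAs,
#' tRNAs, the control region / D-loop, and intergenic spacers). The
#' control-region interval may wrap the origin (`start > end`). Construction
#' fails unless every position `1..genome_length` is covered exactly once.
#'
#' @param intervals data frame with columns `start`, `end` (1-based,
#'   inclusive), `name`, `biotype`.
#' @param genome_length total genome length (default 16569).
#' @return an object of class `mt_locus_map`.
#' @export
mt_locus_map <- function(intervals, genome_length = 16569L) {
  intervals <- as_tibble(intervals)
  stopifnot(all(c("start", "end", "name", "biotype") %in% names(intervals)))
  L <- as.integer(genome_length)
  idx <- integer(L)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    p <- if (s <= e) s:e else c(s:L, 1:e)
    if (any(idx[p] != 0L)) {
      abort(sprintf("locus map interval '%s' overlaps another interval",
                    intervals$name[i]))
    }
    idx[p] <- i
  }
  if (any(idx == 0L)) {
    abort(sprintf("locus map does not cover position %d", which(idx == 0L)[1]))
  }
  structure(list(intervals = intervals, genome_length = L, index = idx),
            class = "mt_locus_map")
}

#' Read a locus map from 4-column tab-separated text
#'
#' Columns `start`, `end` (1-based inclusive), `name`, `biotype`.
#'
#' @param path TSV path; default is the packaged synthetic map.
#' @inheritParams mt_locus_map
#' @return an [mt_locus_map()] object.
#' @export
read_locus_map <- function(path = NULL, genome_length = 16569L) {
  path <- path %||% system.file("extdata", "mt_locus_map.tsv",
                                package = "paleomt")
  mt_locus_map(read.delim(path, stringsAsFactors = FALSE), genome_length)
}

#' Classify genome positions by locus
#'
#' @param position integer vector of 1-based positions.
#' @param locus_map an [mt_locus_map()].
#' @return tibble with `position`, `locus`, `biotype`.
#' @export
classify_locus <- function(position, locus_map) {
  position <- as.integer(position)
  if (any(position < 1L | position > locus_map$genome_length)) {
    abort("position out of range for locus classification")
  }
  i <- locus_map$index[position]
  tibble(position = position,
         locus = locus_map$intervals$name[i],
         biotype = locus_map$intervals$biotype[i])
}
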