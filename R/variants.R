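# Variant and haplotype representation.

#' Build a normalized mitochondrial variant table
#'
#' Variants are stored left-aligned and minimal, with 1-based reference
#' coordinates (rCRS community numbering). A SNP has both alleles of length
#' one; insertions/deletions carry a shared anchor base.
#'
#' @param position integer vector, 1-based.
#' @param ref_allele,alt_allele character vectors of alleles.
#' @return tibble with `position`, `ref_allele`, `alt_allele`, `vclass`.
#' @export
mt_variants <- function(position, ref_allele, alt_allele) {
  position <- as.integer(position)
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  vclass <- dplyr::case_when(
    nchar(ref_allele) == 1 & nchar(alt_allele) == 1 ~ "SNP",
    nchar(alt_allele) > nchar(ref_allele) ~ "insertion",
    nchar(alt_allele) < nchar(ref_allele) ~ "deletion",
    TRUE ~ "MNP")
  out <- tibble(position = position, ref_allele = ref_allele,
                alt_allele = alt_allele, vclass = vclass)
  dplyr::arrange(out, .data$position)
}

# check a variant table against the reference; abort on mismatch/overlap
validate_variants <- function(ref, variants) {
  if (nrow(variants) == 0) return(invisible(variants))
  variants <- dplyr::arrange(variants, .data$position)
  obs <- substring(ref$sequence, variants$position,
                   variants$position + nchar(variants$ref_allele) - 1L)
  bad <- which(obs != variants$ref_allele)
  if (length(bad)) {
    abort(sprintf(
      "ref allele mismatch at position %d: variant says '%s', reference has '%s'",
      variants$position[bad[1]], variants$ref_allele[bad[1]], obs[bad[1]]))
  }
  ends <- variants$position + nchar(variants$ref_allele) - 1L
  if (nrow(variants) > 1 &&
      any(variants$position[-1] <= ends[-nrow(variants)])) {
    abort("overlapping variants")
  }
  if (anyDuplicated(variants$position)) abort("duplicate variant positions")
  invisible(variants)
}

#' Apply variants to a reference, yielding a haplotype
#'
#' SNPs substitute single bases; indels shift downstream coordinates in the
#' materialized sequence only -- variant coordinates always refer to the
#' reference numbering.
#'
#' @param ref an [mt_reference()].
#' @param variants an [mt_variants()] tibble (may be empty).
#' @return an object of class `mt_haplotype`: `reference`, `variants`,
#'   `sequence`.
#' @export
apply_variants <- function(ref, variants) {
  variants <- as_tibble(variants)
  validate_variants(ref, variants)
  if (nrow(variants) == 0) {
    seqn <- ref$sequence
  } else {
    variants <- dplyr::arrange(variants, .data$position)
    pieces <- character(2 * nrow(variants) + 1)
    cur <- 1L
    for (i in seq_len(nrow(variants))) {
      p <- variants$position[i]
      pieces[2 * i - 1] <- substr(ref$sequence, cur, p - 1L)
      pieces[2 * i] <- variants$alt_allele[i]
      cur <- p + nchar(variants$ref_allele[i])
    }
    pieces[2 * nrow(variants) + 1] <- substr(ref$sequence, cur, ref$length)
    seqn <- paste(pieces, collapse = "")
  }
  structure(list(reference = ref, variants = variants, sequence = seqn),
            class = "mt_haplotype")
}

#' @export
print.mt_haplotype <- function(x, ...) {
  cat(sprintf("<mt_haplotype> %d bp, %d variant(s) on %s\n",
              nchar(x$sequence), nrow(x$variants), x$reference$name))
  invisible(x)
}

#' Diff a SNP-only haplotype against its reference
#'
#' Recovers the SNP set of a haplotype whose sequence has the reference
#' length (no indels).
#'
#' @param haplotype an `mt_haplotype` (from [apply_variants()]).
#' @return an [mt_variants()] tibble.
#' @export
haplotype_diff <- function(haplotype) {
  ref <- haplotype$reference
  if (nchar(haplotype$sequence) != ref$length) {
    abort("haplotype_diff requires a SNP-only haplotype (equal lengths)")
  }
  a <- seq_chars(ref$sequence)
  b <- seq_chars(haplotype$sequence)
  i <- which(a != b)
  mt_variants(i, a[i], b[i])
}

#' Draw a random SNP set for a synthetic haplotype
#'
#' Samples `n` distinct non-`N` positions (optionally forcing specific
#' positions into the set) and assigns each a random alternative base.
#'
#' @param ref an [mt_reference()].
#' @param n number of SNPs.
#' @param seed integer seed.
#' @param include_positions positions that must be among the `n` sites.
#' @return an [mt_variants()] tibble of `n` SNPs.
#' @export
random_snp_set <- function(ref, n, seed, include_positions = integer(0)) {
  withr::with_seed(seed, {
    chars <- seq_chars(ref$sequence)
    ok <- which(chars != "N")
    include_positions <- as.integer(include_positions)
    if (any(chars[include_positions] == "N")) {
      abort("cannot place a SNP on an N position")
    }
    pool <- setdiff(ok, include_positions)
    pos <- sort(c(include_positions,
                  sample(pool, n - length(include_positions))))
    alt <- unname(vapply(chars[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1)))
    mt_variants(pos, chars[pos], alt)
  })
}
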