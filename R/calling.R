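# Pileup construction and per-site variant calling with allele fraction,
# likelihood evidence and filter tags in the style of a somatic caller run
# in mitochondrial mode.

#' Build a base-level pileup over the circular genome
#'
#' Expands retained, non-duplicate alignments with mapping quality at least
#' `min_mq` into per-base observations, dropping bases below `min_bq`.
#' Reverse-strand reads contribute through their reference-forward
#' orientation; the circular wrap is respected.
#'
#' @param alignments tibble from the mapping stage; rows with
#'   `retained == TRUE` (if present) or `mapped == TRUE` are used, minus
#'   flagged duplicates.
#' @param reads reads tibble (`id`, `sequence`, `qualities`).
#' @param ref an [mt_reference()].
#' @param min_bq minimum base quality for a base to be counted (default 20).
#' @param min_mq minimum mapping quality (default 30).
#' @return an object of class `mt_pileup`: per-position depth (`depth`),
#'   a position x allele count matrix (`counts`), and the raw observation
#'   vectors used for evidence computations.
#' @export
build_pileup <- function(alignments, reads, ref, min_bq = 20L, min_mq = 30L) {
  al <- alignments
  use <- if ("retained" %in% names(al)) al$retained else al$mapped
  if ("duplicate" %in% names(al)) use <- use & !al$duplicate
  use <- use & !is.na(al$mapq) & al$mapq >= min_mq & al$target == ref$name
  al <- al[which(use), ]

  L <- ref$length
  if (nrow(al) == 0) {
    raw <- list(pos = integer(0), base = integer(0), fwd = integer(0),
                qual = integer(0), end_dist = integer(0))
    return(structure(list(depth = integer(L),
                          counts = matrix(0L, L, 4,
                                          dimnames = list(NULL, c("A", "C", "G", "T"))),
                          raw = raw, genome_length = L, ref = ref,
                          min_bq = min_bq, min_mq = min_mq),
                     class = "mt_pileup"))
  }
  idx <- match(al$read_id, reads$id)
  seqs <- reads$sequence[idx]
  quals <- reads$qualities[idx]
  neg <- al$strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  quals[neg] <- vapply(strsplit(quals[neg], "", fixed = TRUE),
                       function(v) paste(rev(v), collapse = ""), character(1))
  raw <- cpp_expand_pileup(seqs, 33L, quals, al$start, al$strand, L,
                           as.integer(min_bq))
  depth <- tabulate(raw$pos, nbins = L)
  counts <- matrix(tabulate(raw$pos + L * raw$base, nbins = 4L * L), L, 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  structure(list(depth = depth, counts = counts, raw = raw,
                 genome_length = L, ref = ref,
                 min_bq = min_bq, min_mq = min_mq),
            class = "mt_pileup")
}

#' @export
print.mt_pileup <- function(x, ...) {
  cat(sprintf("<mt_pileup> %d bp genome, mean depth %.1f, %.1f%% covered\n",
              x$genome_length, mean(x$depth), 100 * mean(x$depth >= 1)))
  invisible(x)
}

#' Per-site counts as a tibble
#'
#' One row per (position, allele) with a positive count.
#'
#' @param x an `mt_pileup`.
#' @param ... unused.
#' @return tibble with `position`, `depth`, `allele`, `count`, `fwd`,
#'   `rev`.
#' @export
as_tibble.mt_pileup <- function(x, ...) {
  nz <- which(x$counts > 0, arr.ind = TRUE)
  fwdc <- matrix(tabulate(x$raw$pos[x$raw$fwd == 1L] +
                            x$genome_length * x$raw$base[x$raw$fwd == 1L],
                          nbins = 4L * x$genome_length),
                 x$genome_length, 4)
  tibble(position = nz[, 1],
         depth = x$depth[nz[, 1]],
         allele = c("A", "C", "G", "T")[nz[, 2]],
         count = x$counts[nz],
         fwd = fwdc[nz],
         rev = x$counts[nz] - fwdc[nz]) |>
    dplyr::arrange(.data$position, .data$allele)
}

#' Call candidate variants from a pileup
#'
#' For each non-reference allele with at least one supporting base, the
#' allele fraction is estimated as `count / DP` and a log10 likelihood
#' ratio (lod) is computed by comparing the two-component model (allele
#' present at the estimated fraction) against the errors-only model, using
#' each base's own error probability `e = 10^(-q/10)` with
#' `P(wrong base) = e/3`. A candidate is emitted iff `lod >= 0`.
#' Multi-allele sites emit one candidate per allele. Sites where the
#' reference base is `N` are not callable (blacklist territory).
#'
#' @param pileup an `mt_pileup`.
#' @return tibble of candidate calls: `position`, `ref_allele`,
#'   `alt_allele`, `AD`, `RD`, `DP`, `AF`, `lod`, strand counts,
#'   `median_end_distance`, `vclass`.
#' @export
call_variants <- function(pileup) {
  ref <- pileup$ref
  L <- pileup$genome_length
  bases <- c("A", "C", "G", "T")
  ref_code <- match(seq_chars(ref$sequence), bases)  # NA for N

  cand <- which(pileup$counts > 0, arr.ind = TRUE)
  keep <- !is.na(ref_code[cand[, 1]]) & cand[, 2] != ref_code[cand[, 1]]
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_calls())

  pos_set <- unique(cand[, 1])
  sel <- which(pileup$raw$pos %in% pos_set)
  obs <- list(pos = pileup$raw$pos[sel], base = pileup$raw$base[sel] + 1L,
              fwd = pileup$raw$fwd[sel], qual = pileup$raw$qual[sel],
              end_dist = pileup$raw$end_dist[sel])
  by_pos <- split(seq_along(obs$pos), obs$pos)

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, 1]; a <- cand[i, 2]
    rc <- ref_code[p]
    j <- by_pos[[as.character(p)]]
    b <- obs$base[j]; e <- 10^(-obs$qual[j] / 10)
    dp <- pileup$depth[p]
    ad <- unname(pileup$counts[p, a])
    rd <- unname(pileup$counts[p, rc])
    af <- ad / dp
    # two-hypothesis per-base likelihoods
    p_alt <- ifelse(b == a, 1 - e, e / 3)
    p_ref <- ifelse(b == rc, 1 - e, e / 3)
    lod <- sum(log10((af * p_alt + (1 - af) * p_ref) / p_ref))
    isalt <- b == a
    rows[[i]] <- tibble(
      position = p, ref_allele = bases[rc], alt_allele = bases[a],
      AD = ad, RD = rd, DP = dp, AF = af, lod = lod,
      alt_fwd = sum(isalt & obs$fwd[j] == 1L),
      alt_rev = sum(isalt & obs$fwd[j] == 0L),
      ref_fwd = sum(b == rc & obs$fwd[j] == 1L),
      ref_rev = sum(b == rc & obs$fwd[j] == 0L),
      median_end_distance = median(obs$end_dist[j][isalt]),
      vclass = "SNP")
  }
  out <- dplyr::bind_rows(rows)
  out <- out[out$lod >= 0, ]
  dplyr::arrange(out, .data$position, .data$alt_allele)
}

empty_calls <- function() {
  tibble(position = integer(0), ref_allele = character(0),
         alt_allele = character(0), AD = integer(0), RD = integer(0),
         DP = integer(0), AF = numeric(0), lod = numeric(0),
         alt_fwd = integer(0), alt_rev = integer(0), ref_fwd = integer(0),
         ref_rev = integer(0), median_end_distance = numeric(0),
         vclass = character(0))
}

#' Tag candidate calls with quality filters
#'
#' Cumulative tags: `low_af` (AF below `min_af`), `position_bias` (median
#' distance of the variant from the nearer read end below
#' `min_median_end`), `strand_bias` (two-sided exact conditional test on
#' the strand 2x2 table significant at `sb_p` *and* alt support confined
#' to one strand), `contamination` (AF within two binomial standard errors
#' of the contamination rate `cr`, applied to minor alleles only -- a
#' majority allele is never discarded as contaminant), `weak_evidence`
#' (negative lod). `PASS` when no tag applies.
#'
#' @param calls tibble from [call_variants()] (or [read_vcf()]).
#' @param cr contamination rate in `[0, 1)`.
#' @param min_af minimum allele fraction (default 0.05).
#' @param min_median_end minimum median distance from the read end
#'   (default 3).
#' @param sb_p strand-bias significance threshold (default 1e-3).
#' @return `calls` with `filters` (semicolon-joined tags or `"PASS"`) and
#'   `cr_used`.
#' @export
apply_call_filters <- function(calls, cr = 0, min_af = 0.05,
                               min_median_end = 3, sb_p = 1e-3) {
  stopifnot(cr >= 0, cr < 1)
  n <- nrow(calls)
  tags <- vector("list", n)
  sb <- rep(FALSE, n)
  one_strand <- (calls$alt_fwd == 0L | calls$alt_rev == 0L) &
    (calls$alt_fwd + calls$alt_rev) > 0L
  for (i in which(one_strand)) {
    m <- matrix(c(calls$alt_fwd[i], calls$alt_rev[i],
                  calls$ref_fwd[i], calls$ref_rev[i]), 2)
    sb[i] <- fisher.test(m)$p.value < sb_p
  }
  low_af <- calls$AF < min_af
  pos_bias <- !is.na(calls$median_end_distance) &
    calls$median_end_distance < min_median_end
  contam <- calls$AF < 0.5 &
    calls$AF <= cr + 2 * sqrt(calls$AF * (1 - calls$AF) / calls$DP)
  weak <- calls$lod < 0
  f <- character(n)
  for (i in seq_len(n)) {
    t <- c(if (low_af[i]) "low_af", if (pos_bias[i]) "position_bias",
           if (sb[i]) "strand_bias", if (contam[i]) "contamination",
           if (weak[i]) "weak_evidence")
    f[i] <- if (length(t)) paste(t, collapse = ";") else "PASS"
  }
  calls$filters <- f
  calls$cr_used <- cr
  calls
}

#' Normalize variant representation
#'
#' Splits multiallelic records (comma-separated `alt_allele`) into
#' per-allele records sharing `DP`, left-aligns indels against the
#' reference and reduces every record to its minimal representation.
#' Idempotent on already-minimal records.
#'
#' @param calls calls tibble (`position`, `ref_allele`, `alt_allele`, ...).
#' @param ref an [mt_reference()].
#' @return normalized calls tibble.
#' @export
normalize_variants <- function(calls, ref) {
  if (nrow(calls) == 0) return(calls)
  # split multiallelics
  calls <- tidyr::separate_rows(calls, "alt_allele", sep = ",")
  for (i in seq_len(nrow(calls))) {
    v <- normalize_one(calls$position[i], calls$ref_allele[i],
                       calls$alt_allele[i], ref)
    calls$position[i] <- v[[1]]
    calls$ref_allele[i] <- v[[2]]
    calls$alt_allele[i] <- v[[3]]
  }
  if ("vclass" %in% names(calls)) {
    calls$vclass <- dplyr::case_when(
      nchar(calls$ref_allele) == 1 & nchar(calls$alt_allele) == 1 ~ "SNP",
      nchar(calls$alt_allele) > nchar(calls$ref_allele) ~ "insertion",
      nchar(calls$alt_allele) < nchar(calls$ref_allele) ~ "deletion",
      TRUE ~ "MNP")
  }
  dplyr::arrange(calls, .data$position, .data$alt_allele)
}

# minimal, left-aligned representation of a single variant
normalize_one <- function(pos, refa, alta, ref) {
  obs <- substr(ref$sequence, pos, pos + nchar(refa) - 1L)
  if (obs != refa) {
    abort(sprintf("inconsistent ref allele at %d: '%s' vs reference '%s'",
                  pos, refa, obs))
  }
  r <- seq_chars(refa); a <- seq_chars(alta)
  repeat {
    # trim shared trailing base
    if (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
      next
    }
    # left-shift an indel whose last bases agree, pulling in the previous
    # reference base
    if (length(r) != length(a) && r[length(r)] == a[length(a)] && pos > 1) {
      prev <- substr(ref$sequence, pos - 1L, pos - 1L)
      r <- c(prev, r[-length(r)]); a <- c(prev, a[-length(a)])
      pos <- pos - 1L
      next
    }
    break
  }
  # trim shared leading bases (keep at least one for indels)
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos, paste(r, collapse = ""), paste(a, collapse = ""))
}
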