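# Read mapping to the circular reference plus decoys, deduplication,
# ambiguity filtering, damage-profile estimation and quality rescaling.
#
# Alignment is ungapped (substitutions only): 110 bp aDNA fragments rarely
# need gaps, and indel calls from externally supplied SAM/VCF remain
# supported downstream. The search is exhaustive over every placement with
# at most `max_mismatch` substitutions on both strands of all targets
# (implemented as a pigeonhole-seeded exact k-mer search, equivalent to the
# brute-force minimum-mismatch scan). Circular placements are canonicalized
# to a start in 1..L, reproducing elongated-reference mapping plus
# circular realignment.

#' Map reads to the circular reference and decoy set
#'
#' Admission contract: reads must be at least `min_length` bp with mean
#' base quality (rounded to the nearest integer) at least `min_mean_bq`,
#' and not degenerate (all-N). Mapping quality follows the convention:
#' 37 for a unique best placement with fewer than 2 mismatches, 30 for a
#' unique best placement with 2 or more (unique placements survive the
#' MQ >= 30 retention rule regardless of mismatch count, as with BWA's
#' unique-hit quality), 0 for ties.
#'
#' @param reads tibble with `id`, `sequence`, `qualities`.
#' @param ref an [mt_reference()].
#' @param decoys optional decoy tibble from [generate_numts_decoys()] (or
#'   any tibble with `name`, `sequence`).
#' @param max_mismatch maximum substitutions for a reportable placement
#'   (default 4).
#' @param min_length,min_mean_bq admission thresholds (defaults 30 and 30).
#' @return tibble with one row per read: `read_id`, `mapped`,
#'   `reject_reason`, `target`, `start` (1-based, canonical on the circle),
#'   `strand`, `mismatches`, `mapq`, `n_best`, `second_best_mismatches`.
#' @export
map_reads <- function(reads, ref, decoys = NULL, max_mismatch = 4L,
                      min_length = 30L, min_mean_bq = 30L) {
  stopifnot(inherits(ref, "mt_reference"))
  n <- nrow(reads)
  lens <- nchar(reads$sequence)
  meanq <- vapply(qual_to_int(reads$qualities), function(v) mean(v), numeric(1))
  all_n <- !grepl("[ACGT]", reads$sequence)
  reject <- dplyr::case_when(
    lens < min_length ~ "too_short",
    round(meanq) < min_mean_bq ~ "low_quality",
    all_n ~ "degenerate",
    TRUE ~ NA_character_)
  admit <- is.na(reject)

  tnames <- c(ref$name, decoys$name)
  tseqs <- c(ref$sequence, decoys$sequence)
  circ <- c(TRUE, rep(FALSE, length(decoys$name)))
  res <- cpp_map_reads(reads$sequence[admit], tseqs, tnames, circ,
                       as.integer(max_mismatch))

  out <- tibble(read_id = reads$id, mapped = FALSE, reject_reason = reject,
                target = NA_character_, start = NA_integer_,
                strand = NA_character_, mismatches = NA_integer_,
                mapq = NA_integer_, n_best = NA_integer_,
                second_best_mismatches = NA_integer_)
  out$target[admit] <- res$target
  out$start[admit] <- res$start
  out$strand[admit] <- res$strand
  out$mismatches[admit] <- res$mismatches
  out$n_best[admit] <- res$n_best
  out$second_best_mismatches[admit] <- res$second_best_mismatches
  out$mapped <- !is.na(out$target)
  out$reject_reason[admit & !out$mapped] <- "unmapped"
  out$mapq <- dplyr::case_when(
    !out$mapped ~ NA_integer_,
    out$n_best > 1L ~ 0L,
    out$mismatches < 2L ~ 37L,
    TRUE ~ 30L)
  out
}

#' Flag PCR duplicates among alignments
#'
#' Reads sharing (target, start, end, strand) collapse to one
#' representative: the highest summed base quality, ties broken by the
#' lexicographically smallest read id.
#'
#' @param alignments tibble from [map_reads()] (mapped rows are
#'   considered).
#' @param reads reads tibble (for qualities and lengths).
#' @return `alignments` with a logical `duplicate` column.
#' @export
deduplicate <- function(alignments, reads) {
  al <- dplyr::left_join(
    alignments,
    tibble(read_id = reads$id,
           .len = nchar(reads$sequence),
           .sumq = vapply(qual_to_int(reads$qualities), sum, numeric(1))),
    by = "read_id")
  al$.end <- al$start + al$.len - 1L
  # survivor rule: max summed quality, tie -> lexicographically least id
  key <- paste(al$target, al$start, al$.end, al$strand)
  keep <- rep(FALSE, nrow(al))
  for (grp in split(seq_len(nrow(al)), key)) {
    g <- grp[al$mapped[grp]]
    if (!length(g)) next
    best <- g[order(-al$.sumq[g], al$read_id[g])][1]
    keep[best] <- TRUE
  }
  al$duplicate <- al$mapped & !keep
  al$.len <- NULL; al$.sumq <- NULL; al$.end <- NULL
  al
}

#' Retain uniquely mt-mapped, unambiguous alignments
#'
#' Mirrors unique-mapping NumtS exclusion: keep only alignments whose best
#' placement is unique, on the mitochondrial target, with any runner-up
#' placement worse by more than `delta` mismatches, and mapping quality at
#' least `min_mapq`. Removed reads are labelled by reason (`decoy-best`,
#' `tie`, `suboptimal-close`, `low-mapq`).
#'
#' @param alignments tibble from [map_reads()] (optionally after
#'   [deduplicate()]).
#' @param delta required margin of the runner-up (default 0: any equal-best
#'   secondary placement disqualifies).
#' @param min_mapq minimum mapping quality (default 30).
#' @param mt_name mitochondrial target name (default taken from the most
#'   frequent target).
#' @return `alignments` with logical `retained` and `removed_reason`
#'   columns; duplicates (if flagged) are not retained.
#' @export
filter_ambiguous <- function(alignments, delta = 0L, min_mapq = 30L,
                             mt_name = NULL) {
  mt_name <- mt_name %||% names(sort(table(alignments$target),
                                     decreasing = TRUE))[1]
  al <- alignments
  dup <- if ("duplicate" %in% names(al)) al$duplicate else FALSE
  reason <- dplyr::case_when(
    !al$mapped ~ "unmapped",
    dup ~ "duplicate",
    al$target != mt_name ~ "decoy-best",
    al$n_best > 1L ~ "tie",
    !is.na(al$second_best_mismatches) &
      al$second_best_mismatches <= al$mismatches + delta ~ "suboptimal-close",
    al$mapq < min_mapq ~ "low-mapq",
    TRUE ~ NA_character_)
  al$retained <- is.na(reason)
  al$removed_reason <- reason
  al
}

#' Estimate the terminal misincorporation (damage) profile
#'
#' For each offset from the read 5' end, the C>T rate among reference-C
#' sites; symmetrically, G>A from the 3' end. Profiles are computed in
#' read orientation (reverse-strand alignments contribute through the
#' reverse-complemented reference window), from retained alignments only.
#' Zero denominators give `NA` rates, not 0.
#'
#' @param alignments tibble with `retained` (or all mapped rows used).
#' @param reads reads tibble.
#' @param ref an [mt_reference()].
#' @param window offsets to profile (default 12).
#' @return an object of class `mt_damage_profile`: tibble with `offset`
#'   (0-based), `rate5_CT`, `n5_C`, `rate3_GA`, `n3_G`.
#' @export
estimate_damage_profile <- function(alignments, reads, ref, window = 12L) {
  al <- alignments[if ("retained" %in% names(alignments))
                     alignments$retained else alignments$mapped, ]
  if (nrow(al) == 0) abort("no retained alignments to profile")
  al <- dplyr::left_join(al, reads[, c("id", "sequence")],
                         by = c(read_id = "id"))
  lens <- nchar(al$sequence)
  refwin <- substring(circular_substr(ref, al$start, max(lens)), 1L, lens)
  neg <- al$strand == "-"
  refwin[neg] <- revcomp(refwin[neg])

  w <- as.integer(window)
  n5C <- n5CT <- n3G <- n3GA <- integer(w)
  for (j in seq_len(w)) {
    rb5 <- substr(refwin, j, j)
    ob5 <- substr(al$sequence, j, j)
    n5C[j] <- sum(rb5 == "C")
    n5CT[j] <- sum(rb5 == "C" & ob5 == "T")
    p3 <- lens - j + 1L
    rb3 <- substring(refwin, p3, p3)
    ob3 <- substring(al$sequence, p3, p3)
    n3G[j] <- sum(rb3 == "G")
    n3GA[j] <- sum(rb3 == "G" & ob3 == "A")
  }
  out <- tibble(offset = 0:(w - 1L),
                rate5_CT = ifelse(n5C > 0, n5CT / n5C, NA_real_), n5_C = n5C,
                rate3_GA = ifelse(n3G > 0, n3GA / n3G, NA_real_), n3_G = n3G)
  class(out) <- c("mt_damage_profile", class(out))
  out
}

#' Downscale base qualities at likely damaged positions
#'
#' For read bases that are T over a reference C within the 5' window (and A
#' over a reference G within the 3' window), the base quality is replaced
#' by `q' = -10 log10(d + 10^(-q/10))` (floored to an integer), where `d`
#' is the estimated damage rate at that offset. `q'` never exceeds `q`;
#' all other bases are untouched.
#'
#' @param reads reads tibble.
#' @param alignments alignments tibble (retained/mapped rows are rescaled).
#' @param profile an [estimate_damage_profile()] result.
#' @param ref an [mt_reference()].
#' @return `reads` with updated `qualities`.
#' @export
rescale_qualities <- function(reads, alignments, profile, ref) {
  al <- alignments[if ("retained" %in% names(alignments))
                     alignments$retained else alignments$mapped, ]
  if (nrow(al) == 0) return(reads)
  idx <- match(al$read_id, reads$id)
  seqs <- reads$sequence[idx]
  quals <- reads$qualities[idx]
  lens <- nchar(seqs)
  refwin <- substring(circular_substr(ref, al$start, max(lens)), 1L, lens)
  neg <- al$strand == "-"
  refwin[neg] <- revcomp(refwin[neg])

  w <- nrow(profile)
  r5 <- ifelse(is.na(profile$rate5_CT), 0, profile$rate5_CT)
  r3 <- ifelse(is.na(profile$rate3_GA), 0, profile$rate3_GA)
  for (j in seq_len(w)) {
    hit5 <- substr(refwin, j, j) == "C" & substr(seqs, j, j) == "T"
    if (any(hit5) && r5[j] > 0) {
      qh <- quals[hit5]
      q <- utf8ToInt(paste(substr(qh, j, j), collapse = "")) - 33L
      qn <- pmax(0L, as.integer(floor(-10 * log10(r5[j] + 10^(-q / 10)))))
      substr(qh, j, j) <- intToUtf8(qn + 33L, multiple = TRUE)
      quals[hit5] <- qh
    }
    p3 <- lens - j + 1L
    hit3 <- substring(refwin, p3, p3) == "G" & substring(seqs, p3, p3) == "A"
    if (any(hit3) && r3[j] > 0) {
      pp <- p3[hit3]
      q <- utf8ToInt(paste(substring(quals[hit3], pp, pp), collapse = "")) - 33L
      qn <- pmax(0L, as.integer(floor(-10 * log10(r3[j] + 10^(-q / 10)))))
      qh <- quals[hit3]
      for (k in seq_along(qh)) substr(qh[k], pp[k], pp[k]) <- intToUtf8(qn[k] + 33L)
      quals[hit3] <- qh
    }
  }
  reads$qualities[idx] <- quals
  reads
}
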