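# Filter-grid application, multiallelic resolution, consensus assembly and
# coverage statistics.

#' A filter pattern (one row of the tested grid)
#'
#' Patterns combine a contamination-rate mode (`none`, `mean` or
#' `highest`), a minimum variant allele depth, a minimum allele fraction
#' (5 or 50 percent) and a minimum site depth. `expert = TRUE` lifts the
#' grid restrictions and accepts arbitrary thresholds.
#'
#' @param cr_mode `"none"`, `"mean"` or `"highest"` -- which supplied
#'   contamination-rate scalar is re-applied through the contamination
#'   rule.
#' @param min_ad minimum alt allele depth (`NA` for none; grid values
#'   2, 3, 5, 10).
#' @param min_af_pct minimum allele fraction in percent (grid: 5 or 50).
#' @param min_dp minimum total depth (`NA` for none; grid values
#'   3, 4, 5, 10, 20).
#' @param expert allow values outside the tested grid.
#' @return object of class `filter_pattern`.
#' @export
filter_pattern <- function(cr_mode = c("none", "mean", "highest"),
                           min_ad = NA, min_af_pct = 50, min_dp = NA,
                           expert = FALSE) {
  cr_mode <- match.arg(cr_mode)
  if (!expert) {
    if (!is.na(min_ad) && !min_ad %in% c(2, 3, 5, 10)) {
      abort("min_ad outside the tested grid (2, 3, 5, 10); use expert = TRUE")
    }
    if (!min_af_pct %in% c(5, 50)) {
      abort("min_af_pct outside the tested grid (5, 50); use expert = TRUE")
    }
    if (!is.na(min_dp) && !min_dp %in% c(3, 4, 5, 10, 20)) {
      abort("min_dp outside the tested grid (3, 4, 5, 10, 20); use expert = TRUE")
    }
  }
  structure(list(cr_mode = cr_mode, min_ad = min_ad,
                 min_af_pct = min_af_pct, min_dp = min_dp),
            class = "filter_pattern")
}

#' @export
print.filter_pattern <- function(x, ...) {
  cat(sprintf("<filter_pattern> CR=%s AD>=%s AF>=%s%% DP>=%s\n", x$cr_mode,
              ifelse(is.na(x$min_ad), "-", x$min_ad), x$min_af_pct,
              ifelse(is.na(x$min_dp), "-", x$min_dp)))
  invisible(x)
}

#' The full 30-pattern filter grid
#'
#' All combinations tested in the benchmark: AD in {none,2,3,5,10} crossed
#' with AF in {5,50} and the paired DP values, plus the mean/highest
#' contamination-rate patterns at AF 50.
#'
#' @return tibble with columns `cr_mode`, `min_ad`, `min_af_pct`,
#'   `min_dp` and a `pattern` list-column of [filter_pattern()] objects.
#' @export
pattern_grid <- function() {
  g <- dplyr::bind_rows(
    tidyr::expand_grid(cr_mode = "none",
                       ad = list(c(NA, 3), c(2, 4), c(3, 5), c(5, 10), c(10, 20)),
                       min_af_pct = c(5, 50), with_dp = c(TRUE, FALSE)),
    tidyr::expand_grid(cr_mode = c("mean", "highest"),
                       ad = list(c(NA, NA), c(2, NA), c(3, NA), c(5, NA), c(10, NA)),
                       min_af_pct = 50, with_dp = FALSE))
  g$min_ad <- vapply(g$ad, `[`, numeric(1), 1)
  g$min_dp <- ifelse(g$with_dp, vapply(g$ad, `[`, numeric(1), 2), NA)
  g <- g[, c("cr_mode", "min_ad", "min_af_pct", "min_dp")]
  g$pattern <- purrr::pmap(g, function(cr_mode, min_ad, min_af_pct, min_dp) {
    filter_pattern(cr_mode, min_ad, min_af_pct, min_dp)
  })
  g
}

#' Apply a filter pattern to tagged calls
#'
#' Retains `PASS` calls meeting the pattern's AD/DP/AF thresholds; when
#' `cr_mode` is not `"none"`, the corresponding contamination-rate scalar
#' is re-applied through the contamination rule of
#' [apply_call_filters()] first.
#'
#' @param calls calls tibble carrying `AD`, `DP`, `AF` and `filters`.
#' @param pattern a [filter_pattern()].
#' @param cr_mean,cr_high contamination-rate scalars selected by
#'   `cr_mode`.
#' @return the retained calls.
#' @export
apply_pattern <- function(calls, pattern, cr_mean = 0, cr_high = 0) {
  stopifnot(inherits(pattern, "filter_pattern"))
  if (pattern$cr_mode != "none" && nrow(calls)) {
    cr <- if (pattern$cr_mode == "mean") cr_mean else cr_high
    contam <- calls$AF < 0.5 &
      calls$AF <= cr + 2 * sqrt(calls$AF * (1 - calls$AF) / calls$DP)
    add <- contam & !grepl("contamination", calls$filters)
    calls$filters[add] <- ifelse(calls$filters[add] == "PASS",
                                 "contamination",
                                 paste0(calls$filters[add], ";contamination"))
  }
  keep <- calls$filters == "PASS" &
    (is.na(pattern$min_ad) | calls$AD >= pattern$min_ad) &
    (is.na(pattern$min_dp) | calls$DP >= pattern$min_dp) &
    calls$AF >= pattern$min_af_pct / 100
  calls[keep, ]
}

#' Resolve multiallelic sites to a single allele
#'
#' After pattern filtering, a site with exactly one surviving alternative
#' keeps it; a site where two or more alternatives survive reports the
#' reference (true multiallelic sites are rare); zero survivors means
#' reference.
#'
#' @param calls retained calls (output of [apply_pattern()]).
#' @return calls with at most one row per position.
#' @export
resolve_multiallelic <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  calls |>
    dplyr::group_by(.data$position) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
}

#' Assemble a consensus sequence from resolved calls
#'
#' Each retained variant is substituted into the reference; sites with
#' post-filter depth 0 become `N`; every other site keeps the reference
#' base. Indels are inserted after SNPs in descending position order so
#' reference-based coordinates stay valid.
#'
#' @param ref an [mt_reference()].
#' @param calls resolved one-allele-per-site calls.
#' @param depth integer vector of post-filter depth per reference
#'   position (e.g. `pileup$depth`), or `NULL` for full coverage.
#' @return object of class `mt_consensus`: `sequence`,
#'   `inserted_variants`, `coverage_pct`, `mean_depth`.
#' @export
build_consensus <- function(ref, calls, depth = NULL) {
  depth <- depth %||% rep(1L, ref$length)
  stopifnot(length(depth) == ref$length)
  if (anyDuplicated(calls$position)) {
    abort("build_consensus requires one allele per site (resolve first)")
  }
  chars <- seq_chars(ref$sequence)
  chars[depth == 0L] <- "N"
  snps <- calls[nchar(calls$ref_allele) == 1 & nchar(calls$alt_allele) == 1, ]
  chars[snps$position] <- snps$alt_allele
  seqn <- paste(chars, collapse = "")
  indels <- calls[nchar(calls$ref_allele) != nchar(calls$alt_allele), ]
  if (nrow(indels)) {
    spans <- indels$position + nchar(indels$ref_allele) - 1L
    o <- order(indels$position)
    if (any(indels$position[o][-1] <= spans[o][-nrow(indels)])) {
      abort("overlapping indel insertions; conflicting records present")
    }
    for (i in order(-indels$position)) {
      p <- indels$position[i]
      seqn <- paste0(substr(seqn, 1, p - 1L), indels$alt_allele[i],
                     substr(seqn, p + nchar(indels$ref_allele[i]),
                            nchar(seqn)))
    }
  }
  stats <- coverage_stats(depth)
  structure(list(sequence = seqn, inserted_variants = calls,
                 coverage_pct = stats$coverage_pct,
                 mean_depth = stats$mean_depth, reference = ref),
            class = "mt_consensus")
}

#' @export
print.mt_consensus <- function(x, ...) {
  cat(sprintf(
    "<mt_consensus> %d bp, %d variant(s) inserted, %.2f%% covered, mean depth %.2f\n",
    nchar(x$sequence), nrow(x$inserted_variants), x$coverage_pct,
    x$mean_depth))
  invisible(x)
}

#' Write a consensus as single-record FASTA
#'
#' @param consensus an `mt_consensus`.
#' @param path output path.
#' @param name record name.
#' @export
write_consensus <- function(consensus, path, name = "consensus") {
  write_fasta(consensus$sequence, path, name = name)
}

#' Coverage statistics from a depth map
#'
#' @param depth integer vector of per-position depth after all read
#'   filters.
#' @return tibble with `coverage_pct` (percent of sites with depth >= 1)
#'   and `mean_depth`.
#' @export
coverage_stats <- function(depth) {
  tibble(coverage_pct = 100 * mean(depth >= 1L),
         mean_depth = mean(depth))
}
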