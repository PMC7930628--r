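# Whole-genome confusion-matrix comparison of a call set against a
# truth/reference variant set, with nine derived statistics and exclusion
# lists. Every genome site is classified exactly once, so
# TP + TN + FP + FN always equals the genome length.

#' Position exclusion lists
#'
#' `blacklist` covers artifact positions (the recurrent miscall around the
#' `N` placeholder at 3107); `rcrs_rare` covers the rare-polymorphism
#' positions of the rCRS that some callers silently suppress (1189, 4769,
#' 7028, 8860 by default; user-extensible).
#'
#' @param blacklist integer positions (default 3107).
#' @param rcrs_rare integer positions (default the four named sites).
#' @return object of class `exclusion_lists`.
#' @export
exclusion_lists <- function(blacklist = 3107L,
                            rcrs_rare = c(1189L, 4769L, 7028L, 8860L)) {
  structure(list(blacklist = as.integer(blacklist),
                 rcrs_rare = as.integer(rcrs_rare)),
            class = "exclusion_lists")
}

#' Classify a call set against a reference set over the whole genome
#'
#' Both sets are position -> allele maps of retained variants. Exclusion
#' positions are removed from both sets before classification (those sites
#' count as true negatives). `TP` = sites where both sets carry the same
#' alternative allele; `FP` = test-only sites, plus shared positions with
#' discordant alleles (the test called a wrong variant there -- the missed
#' reference allele is noted in a side report); `FN` = reference-only
#' sites; `TN` = all remaining sites. Indel records are attributed to
#' their anchor position.
#'
#' @param test_set,reference_set tibbles with `position`, `alt_allele`
#'   (and optionally `ref_allele`).
#' @param exclusions an [exclusion_lists()].
#' @param genome_length total genome length (default 16569).
#' @param mismatch_as character: count a shared-position allele mismatch
#'   as `"FP"` (default) -- counting it as both FP and FN would break the
#'   sums-to-genome invariant.
#' @return object of class `mt_confusion`: `TP`, `TN`, `FP`, `FN`,
#'   `genome_length`, plus a `mismatches` side report.
#' @export
classify_calls <- function(test_set, reference_set,
                           exclusions = exclusion_lists(),
                           genome_length = 16569L,
                           mismatch_as = c("FP", "FN")) {
  mismatch_as <- match.arg(mismatch_as)
  check_set <- function(s, what) {
    if (any(s$position < 1L | s$position > genome_length)) {
      abort(sprintf("%s set has a position outside the genome", what))
    }
    if (anyDuplicated(s$position)) {
      abort(sprintf("%s set has duplicate positions", what))
    }
  }
  check_set(test_set, "test"); check_set(reference_set, "reference")
  excl <- unique(c(exclusions$blacklist, exclusions$rcrs_rare))
  test <- test_set[!test_set$position %in% excl, ]
  refs <- reference_set[!reference_set$position %in% excl, ]

  shared <- intersect(test$position, refs$position)
  t_alt <- setNames(test$alt_allele, test$position)[as.character(shared)]
  r_alt <- setNames(refs$alt_allele, refs$position)[as.character(shared)]
  agree <- t_alt == r_alt
  tp <- sum(agree)
  mism <- shared[!agree]
  fp <- length(setdiff(test$position, refs$position))
  fn <- length(setdiff(refs$position, test$position))
  if (mismatch_as == "FP") fp <- fp + length(mism) else fn <- fn + length(mism)
  tn <- genome_length - tp - fp - fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 genome_length = as.integer(genome_length),
                 mismatches = tibble(position = mism,
                                     test_allele = t_alt[!agree],
                                     reference_allele = r_alt[!agree])),
            class = "mt_confusion")
}

#' @export
print.mt_confusion <- function(x, ...) {
  cat(sprintf("<mt_confusion> TP %d | TN %d | FP %d | FN %d (genome %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$genome_length))
  invisible(x)
}

#' The nine confusion-derived statistics
#'
#' PPV (precision), SN (sensitivity/recall), SPC (specificity), FNR, FPR,
#' NPV, FDR, FOR and ACC, at full precision. Zero denominators give `NA`
#' for the affected statistic; the rest are computed. Use
#' [format_metrics()] for display rounding.
#'
#' @param counts an `mt_confusion`, or anything with `TP`, `TN`, `FP`,
#'   `FN` fields/columns (e.g. one row of a counts table).
#' @return one-row tibble with `TP`, `TN`, `FP`, `FN` and the nine
#'   statistics.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  ppv <- div(tp, tp + fp)
  sn <- div(tp, tp + fn)
  spc <- div(tn, tn + fp)
  tibble(TP = tp, TN = tn, FP = fp, FN = fn,
         PPV = ppv, SN = sn, SPC = spc,
         FNR = 1 - sn, FPR = div(fp, fp + tn),
         NPV = div(tn, tn + fn), FDR = 1 - ppv,
         FOR = div(fn, fn + tn),
         ACC = (tp + tn) / (tp + tn + fp + fn))
}

metric_cols <- c("PPV", "SN", "SPC", "FNR", "FPR", "NPV", "FDR", "FOR", "ACC")

#' Display-round a metrics table
#'
#' Two decimals for most statistics; FPR and FOR in scientific notation
#' with three significant digits. Rounding happens at display time only.
#'
#' @param metrics tibble from [compute_metrics()].
#' @return tibble of formatted character columns.
#' @export
format_metrics <- function(metrics) {
  out <- metrics
  for (cl in setdiff(metric_cols, c("FPR", "FOR"))) {
    out[[cl]] <- sprintf("%.2f", metrics[[cl]])
  }
  for (cl in c("FPR", "FOR")) {
    out[[cl]] <- toupper(sprintf("%.2e", metrics[[cl]]))
  }
  out
}

#' Aggregate per-sample metrics
#'
#' Arithmetic mean and median per column over per-sample values (never
#' recomputed from pooled counts).
#'
#' @param per_sample tibble of per-sample rows from [compute_metrics()]
#'   (extra identifier columns are preserved as `NA` in the summary rows).
#' @return tibble with two rows, `Mean` and `Median`.
#' @export
aggregate_metrics <- function(per_sample) {
  stopifnot(nrow(per_sample) >= 1)
  num <- names(per_sample)[vapply(per_sample, is.numeric, logical(1))]
  mk <- function(fn, label) {
    row <- purrr::map(per_sample, function(col) {
      if (is.numeric(col)) fn(col, na.rm = TRUE) else NA
    })
    row <- as_tibble(row)
    row$statistic <- label
    row
  }
  dplyr::bind_rows(mk(function(x, ...) mean(x, ...), "Mean"),
                   mk(function(x, ...) median(x, ...), "Median")) |>
    dplyr::relocate("statistic")
}

#' @rdname compute_metrics
#' @param x an `mt_confusion`.
#' @param ... unused.
#' @export
tidy.mt_confusion <- function(x, ...) {
  m <- compute_metrics(x)
  tidyr::pivot_longer(m, dplyr::all_of(metric_cols),
                      names_to = "metric", values_to = "value") |>
    dplyr::select("metric", "value")
}

#' @rdname compute_metrics
#' @export
glance.mt_confusion <- function(x, ...) {
  compute_metrics(x)
}

#' Packaged benchmark confusion counts
#'
#' Per-sample confusion counts for the 27 ancient Sicilian (Polizzello
#' necropolis) mtDNA samples used to validate the filtering pipeline, and
#' the simulation-grid counts (contamination titration and 30:70
#' heteroplasmy designs). Each row sums to the 16,569 bp genome.
#'
#' @param which `"samples"` or `"simulations"`.
#' @return tibble of counts.
#' @export
benchmark_confusion_counts <- function(which = c("samples", "simulations")) {
  which <- match.arg(which)
  f <- if (which == "samples") "polizzello_confusion_counts.tsv"
       else "simulated_confusion_counts.tsv"
  as_tibble(read.delim(system.file("extdata", f, package = "paleomt"),
                       check.names = FALSE))
}
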