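# Heteroplasmy site selection, allele-fraction profiling, base-change
# composition, Ts/Tv and multi-sample sharing summaries.

#' Select potential heteroplasmy sites
#'
#' A site qualifies when both the variant and the reference allele are
#' well supported: `PASS` calls with alt depth and reference depth both at
#' or above the thresholds (inclusive). A homoplasmy (reference depth 0)
#' never qualifies.
#'
#' @param calls tagged calls tibble (must carry `AD`, `RD`, `filters`).
#' @param min_ad,min_rd inclusive thresholds (default 10 and 10).
#' @return the selected calls.
#' @export
select_heteroplasmy_sites <- function(calls, min_ad = 10L, min_rd = 10L) {
  keep <- calls$filters == "PASS" & calls$AD >= min_ad & calls$RD >= min_rd
  calls[keep, ]
}

af_bin_breaks <- c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100)

af_bin_labels <- c("[5,10)", "[10,20)", "[20,30)", "[30,40)", "[40,50)",
                   "[50,60)", "[60,70)", "[70,80)", "[80,90)", "[90,100]")

#' Allele-fraction bin profile
#'
#' Bins selected sites into half-open 10-percent allele-fraction ranges,
#' except the top bin which is closed (`[90,100]`, quasi-homoplasmies).
#' The bottom of the profile is the 5 percent emission floor. Empty input
#' yields an all-zero profile (samples where no variant passes the
#' filters).
#'
#' @param selected calls from [select_heteroplasmy_sites()].
#' @param sample sample identifier attached to the profile.
#' @return object of class `mt_het_profile`: tibble with `bin`, `n`,
#'   `pct`, plus attributes `n_low` (AF < 10 percent), `n_quasi`
#'   (AF >= 90 percent) and `sample`.
#' @export
af_bin_profile <- function(selected, sample = "sample") {
  af <- selected$AF * 100
  if (any(af < 5 - 1e-9)) abort("allele fractions below the 5% emission floor")
  idx <- findInterval(af, af_bin_breaks, rightmost.closed = TRUE)
  n <- tabulate(idx, nbins = 10L)
  out <- tibble(bin = af_bin_labels, n = n,
                pct = if (sum(n) > 0) 100 * n / sum(n) else rep(0, 10))
  class(out) <- c("mt_het_profile", class(out))
  attr(out, "n_low") <- n[1] + n[2]      # AF < 10%
  attr(out, "n_quasi") <- n[10]          # AF >= 90%
  attr(out, "sample") <- sample
  out
}

transitions <- c("A>G", "G>A", "C>T", "T>C")
base_change_classes <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                         "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Base-change composition of SNP calls
#'
#' Counts over the 12 substitution classes in reference-strand
#' orientation, with the shares of type 1 (A>G, T>C) and type 2 (C>T,
#' G>A) transitions -- the damage-enriched classes in ancient DNA.
#'
#' @param calls SNP calls tibble.
#' @return tibble with `change`, `n`, `class` (type1 / type2 /
#'   transversion) plus attributes `type1_share`, `type2_share`.
#' @export
base_change_composition <- function(calls) {
  snp <- calls[nchar(calls$ref_allele) == 1 & nchar(calls$alt_allele) == 1 &
                 calls$ref_allele != "N", ]
  ch <- paste0(snp$ref_allele, ">", snp$alt_allele)
  n <- vapply(base_change_classes, function(x) sum(ch == x), integer(1))
  cls <- dplyr::case_when(
    base_change_classes %in% c("A>G", "T>C") ~ "type1",
    base_change_classes %in% c("C>T", "G>A") ~ "type2",
    TRUE ~ "transversion")
  out <- tibble(change = base_change_classes, n = unname(n), class = cls)
  tot <- sum(out$n)
  attr(out, "type1_share") <- if (tot) sum(out$n[out$class == "type1"]) / tot else NA_real_
  attr(out, "type2_share") <- if (tot) sum(out$n[out$class == "type2"]) / tot else NA_real_
  class(out) <- c("mt_base_changes", class(out))
  out
}

#' Transition/transversion ratio
#'
#' Returns `NA` (the undefined sentinel) when no transversions are
#' present -- never a division by zero. Human mtDNA expectation is around
#' 15.
#'
#' @param calls SNP calls tibble.
#' @return single numeric ratio, or `NA_real_` when undefined.
#' @export
titv_ratio <- function(calls) {
  snp <- calls[nchar(calls$ref_allele) == 1 & nchar(calls$alt_allele) == 1 &
                 calls$ref_allele != "N", ]
  ch <- paste0(snp$ref_allele, ">", snp$alt_allele)
  ts <- sum(ch %in% transitions)
  tv <- nrow(snp) - ts
  if (tv == 0) NA_real_ else ts / tv
}

#' Variant sharing across samples
#'
#' Builds the variant-by-sample occurrence matrix, counts singletons
#' (variants seen in exactly one sample) and, when a locus map is given,
#' the per-locus variant density (variants per kb of locus).
#'
#' @param call_sets named list of per-sample calls tibbles.
#' @param locus_map optional [mt_locus_map()] for per-locus density.
#' @return list with `matrix` (tibble: variant key, one logical column per
#'   sample, `occurrence`), `n_singletons`, and `locus_density` (tibble or
#'   `NULL`).
#' @export
shared_variant_table <- function(call_sets, locus_map = NULL) {
  stopifnot(length(call_sets) >= 1)
  if (is.null(names(call_sets))) {
    names(call_sets) <- paste0("sample", seq_along(call_sets))
  }
  keyed <- purrr::imap(call_sets, function(d, nm) {
    tibble(key = paste0(d$position, d$ref_allele, ">", d$alt_allele),
           position = d$position, sample = nm)
  }) |> dplyr::bind_rows()
  wide <- keyed |>
    dplyr::distinct(.data$key, .data$position, .data$sample) |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "present",
                       values_fill = FALSE)
  occ <- rowSums(as.matrix(wide[, names(call_sets), drop = FALSE]))
  wide$occurrence <- as.integer(occ)
  dens <- NULL
  if (!is.null(locus_map)) {
    loc <- classify_locus(wide$position, locus_map)
    iv <- locus_map$intervals
    ivlen <- ifelse(iv$start <= iv$end, iv$end - iv$start + 1L,
                    locus_map$genome_length - iv$start + 1L + iv$end)
    dens <- loc |>
      dplyr::count(.data$locus, name = "n_variants") |>
      dplyr::left_join(tibble(locus = iv$name, length_bp = ivlen),
                       by = "locus") |>
      dplyr::mutate(density_per_kb = 1000 * .data$n_variants / .data$length_bp)
  }
  list(matrix = wide, n_singletons = sum(occ == 1), locus_density = dens)
}
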