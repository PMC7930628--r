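# ggplot2 displays for the main result types.

#' Plot a damage profile
#'
#' C>T rates by 5' offset and G>A rates by 3' offset, the classic
#' smile-shaped misincorporation display.
#'
#' @param object an `mt_damage_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mt_damage_profile <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object)[, c("offset", "rate5_CT", "rate3_GA")],
                           c("rate5_CT", "rate3_GA"),
                           names_to = "end", values_to = "rate")
  d$end <- ifelse(d$end == "rate5_CT", "5' C>T", "3' G>A")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$rate,
                                  colour = .data$end)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "offset from read end (bp)",
                  y = "misincorporation rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a heteroplasmy allele-fraction profile
#'
#' @param object an `mt_het_profile` from [af_bin_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mt_het_profile <- function(object, ...) {
  d <- as_tibble(object)
  d$bin <- factor(d$bin, levels = af_bin_labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "allele fraction (%)", y = "% of selected variants",
                  title = attr(object, "sample")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot base-change composition
#'
#' @param object an `mt_base_changes` from [base_change_composition()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mt_base_changes <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$change, y = .data$n,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
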