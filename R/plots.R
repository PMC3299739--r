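# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.tss_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Distance from TSS (bp)", y = "Mean window count") +
    ggplot2::theme_minimal()
}

#' Plot a TSS-centered average profile
#'
#' @param profile A `tss_profile` from [tss_profile()].
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  autoplot(profile)
}

#' @exportS3Method ggplot2::autoplot
autoplot.tss_bin_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Bin relative to TSS (downstream positive)",
                  y = "Differential regions") +
    ggplot2::theme_minimal()
}

#' Plot a TSS-relative histogram of differential regions
#'
#' @param hist A `tss_bin_histogram` from [tss_bin_histogram()].
#' @return A ggplot object.
#' @export
plot_tss_histogram <- function(hist) {
  autoplot(hist)
}

#' Plot mark-state categories across expression groups
#'
#' Stacked per-group proportions of the asymmetric categories (mark lost vs
#' gained at condition B), the view used to relate mark turnover to
#' up-/down-regulation.
#'
#' @param crosstab Tibble from [crosstab_states_by_group()].
#' @param mark Mark label (selects the `MARK-None` / `None-MARK` categories).
#' @return A ggplot object.
#' @export
plot_state_crosstab <- function(crosstab, mark) {
  asym <- crosstab |>
    filter(.data$category %in% c(paste0(mark, "-None"), paste0("None-", mark)))
  ggplot2::ggplot(asym, ggplot2::aes(x = .data$group, y = .data$proportion,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = setNames(
      c("#2166ac", "#b2182b"),
      c(paste0(mark, "-None"), paste0("None-", mark))
    )) +
    ggplot2::labs(x = "Expression group (A = highest at condition A)",
                  y = "Proportion of group", fill = "Category") +
    ggplot2::theme_minimal()
}
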