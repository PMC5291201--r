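#' Quantile-quantile plot of scan p-values
#'
#' @param qq Tibble from [qq_points()], or a numeric vector of p-values.
#' @return A ggplot object.
#' @export
plot_qq <- function(qq) {
  if (is.numeric(qq)) qq <- qq_points(qq)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Leave-one-out stability plot
#'
#' Minus-log10 p-value against the variant removed, with a red line at the
#' all-variant reference p-value and a blue line at the significance
#' threshold.
#'
#' @param loo Tibble from [leave_one_out()].
#' @param p_threshold Threshold line (default 1e-14).
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo, p_threshold = 1e-14) {
  d <- filter(loo, .data$removed != "none")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$removed, y = .data$neg_log10_p)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = -log10(d$reference_p[1]),
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), colour = "blue") +
    ggplot2::labs(x = "Variant removed", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Carrier methylation box-data plot
#'
#' Displays the carrier and non-carrier five-number summaries per variant as
#' paired boxes, the data behind carrier outlier inspection.
#'
#' @param summaries Tibble from [carrier_summary()].
#' @return A ggplot object.
#' @export
plot_carrier_summary <- function(summaries) {
  long <- bind_rows(
    mutate(select(summaries, "variant_id", min = "carrier_min",
                  q1 = "carrier_q1", med = "carrier_med", q3 = "carrier_q3",
                  max = "carrier_max"), group = "carrier"),
    mutate(select(summaries, "variant_id", min = "noncarrier_min",
                  q1 = "noncarrier_q1", med = "noncarrier_med",
                  q3 = "noncarrier_q3", max = "noncarrier_max"),
           group = "non-carrier"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant_id, fill = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$med,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity", position = ggplot2::position_dodge(width = 0.8),
      width = 0.6) +
    ggplot2::labs(x = "Variant", y = "Methylation (analysis scale)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
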