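#' Manhattan plot of single-step GWAS results
#'
#' @param results An `ssgwas_result` (or any tibble with `chrom`, `pos_bp`,
#'   `minus_log10_p`).
#' @param thresholds Optional [gwas_thresholds()] drawn as horizontal lines.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, thresholds = NULL) {
  df <- dplyr::filter(results, !is.na(.data$minus_log10_p))
  offsets <- dplyr::summarise(dplyr::group_by(df, .data$chrom),
                              len = max(.data$pos_bp), .groups = "drop")
  offsets$offset <- cumsum(dplyr::lag(offsets$len, default = 0))
  df <- dplyr::left_join(df, offsets[, c("chrom", "offset")], by = "chrom")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pos_bp + .data$offset, y = .data$minus_log10_p,
    colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "Genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p +
      ggplot2::geom_hline(yintercept = thresholds$significant_logp,
                          linetype = "dashed", colour = "red") +
      ggplot2::geom_hline(yintercept = thresholds$suggestive_logp,
                          linetype = "dotted", colour = "darkorange")
  }
  p
}

#' QQ plot of observed versus expected -log10 p-values
#'
#' @param qq QQ tibble from [gwas_tables()].
#' @param inflation Optional inflation factor annotated on the plot.
#' @return A ggplot object.
#' @export
plot_qq <- function(qq, inflation = NULL) {
  p <- ggplot2::ggplot(qq, ggplot2::aes(.data$expected_logp,
                                        .data$observed_logp)) +
    ggplot2::geom_point(size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(inflation)) {
    p <- p + ggplot2::annotate(
      "text", x = min(qq$expected_logp), y = max(qq$observed_logp),
      hjust = 0, label = sprintf("lambda == %.3f", inflation), parse = TRUE)
  }
  p
}

#' LD-decay plot
#'
#' @param ld LD tibble from [compute_ld()].
#' @param bin_bp Bin width for the decay summary curve.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(ld, bin_bp = 1e6) {
  dec <- ld_decay_summary(ld, bin_bp)
  ggplot2::ggplot(dec, ggplot2::aes((.data$bin_start_bp + .data$bin_end_bp) / 2e6,
                                    .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Distance (Mb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot ssgwas_result
#' @export
autoplot.ssgwas_result <- function(object, thresholds = NULL, ...) {
  plot_manhattan(object, thresholds)
}
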