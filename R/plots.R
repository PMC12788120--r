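#' Spectrogram heat map
#'
#' Time x frequency magnitude raster restricted to the low-frequency
#' analysis range.
#'
#' @param object An `emg_spectrogram`.
#' @param fmax Frequency ceiling in Hz (default 14).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_spectrogram <- function(object, fmax = 14, ...) {
  keep <- object$frequencies <= fmax
  df <- tidyr::expand_grid(
    frequency = object$frequencies[keep],
    time = object$times
  )
  df$magnitude <- as.vector(object$magnitudes[keep, , drop = FALSE])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
    fill = .data$magnitude
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "time (s)", y = "frequency (Hz)",
      fill = "magnitude\n(MVC fraction)"
    ) +
    ggplot2::theme_minimal()
}

#' Pairwise standardised test statistics of a battery
#'
#' Bar chart of Dunn standardised test statistics per task pair, faceted by
#' band and measure; bars crossing the two-sided normal critical value at
#' the battery's alpha indicate significant pairs before adjustment.
#'
#' @param object A `tremor_battery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tremor_battery <- function(object, ...) {
  pw <- object$pairwise
  pw$pair <- paste0(pw$group_i, "-", pw$group_j)
  crit <- stats::qnorm(1 - object$alpha / 2)
  ggplot2::ggplot(pw, ggplot2::aes(.data$pair, .data$std_test_statistic,
    fill = .data$adj_sig < object$alpha
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-crit, crit), linetype = "dashed") +
    ggplot2::facet_grid(ggplot2::vars(.data$measure), ggplot2::vars(.data$band),
      scales = "free_x"
    ) +
    ggplot2::labs(
      x = "task pair", y = "standardised test statistic (z)",
      fill = paste0("adj. p < ", object$alpha)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Frequency/magnitude profile of one band across tasks
#'
#' @param band_table Band observation table.
#' @param band Band name to plot.
#' @return A ggplot object.
#' @export
plot_band_profile <- function(band_table, band) {
  sub <- dplyr::filter(band_table, .data$band == !!band)
  long <- tidyr::pivot_longer(sub, c("frequency", "magnitude"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$task_id), .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(
      title = paste0(band, " band"),
      x = "task", y = NULL
    ) +
    ggplot2::theme_minimal()
}
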