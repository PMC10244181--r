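# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trigger-locked time-frequency response
#'
#' @param object a `sleeploop_tfr`.
#' @param ... unused.
#' @return a ggplot: time against frequency, fill = percent power change.
#' @export
autoplot.sleeploop_tfr <- function(object, ...) {
  df <- tidy.sleeploop_tfr(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$pct_change)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from trigger (s)", y = "Frequency (Hz)",
                  fill = "% change") +
    ggplot2::theme_minimal()
}

#' Plot a hypnogram with its NREM posterior
#'
#' @param hypnogram a [score_nrem()] tibble. A Gaussian smoothing of the
#'   posterior trace (sd in epochs, 0 = off) is available for display only;
#'   it plays no part in scoring.
#' @param smooth_sd smoothing bandwidth in epochs (default 0).
#' @return a ggplot.
#' @export
plot_hypnogram <- function(hypnogram, smooth_sd = 0) {
  df <- hypnogram
  if (smooth_sd > 0) {
    k <- stats::dnorm(seq(-3 * smooth_sd, 3 * smooth_sd), sd = smooth_sd)
    k <- k / sum(k)
    p <- df$posterior_nrem
    p[is.na(p)] <- 0.5
    df$posterior_nrem <- as.numeric(stats::filter(p, k, sides = 2))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch_start_s / 60)) +
    ggplot2::geom_step(ggplot2::aes(y = as.numeric(.data$label == "NREM")),
                       color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$posterior_nrem), color = "steelblue",
                       na.rm = TRUE) +
    ggplot2::scale_y_continuous(breaks = c(0, 1), labels = c("DESYNC", "NREM")) +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot detected events over a stretch of signal
#'
#' @param x signal vector (microvolts).
#' @param rate_hz sampling rate.
#' @param events event tibble (`onset_s`, `offset_s`, `kind`).
#' @param window two-element time window in seconds.
#' @return a ggplot.
#' @export
plot_events <- function(x, rate_hz, events, window = c(0, 30)) {
  i0 <- time_to_index(window[1], rate_hz, length(x))
  i1 <- time_to_index(window[2], rate_hz, length(x))
  sig <- tibble::tibble(time_s = (seq(i0, i1) - 1) / rate_hz, uv = x[i0:i1])
  ev <- events[events$onset_s < window[2] & events$offset_s > window[1], , drop = FALSE]
  p <- ggplot2::ggplot(sig, ggplot2::aes(x = .data$time_s, y = .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (uV)") +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE, alpha = 0.25,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf, fill = .data$kind))
  }
  p
}
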