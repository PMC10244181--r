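# broom-style tidiers for the package's fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spike-phase cosine fit
#'
#' @param x a `sleeploop_plfit` from [fit_spike_phase_cosine()].
#' @param ... unused.
#' @return one-row tibble with the fit parameters (`a`, `b`, `c`), `r2`,
#'   `ld`, `rayleigh_p`, `pref_phase_deg`, `phase_category`, `n_spikes`,
#'   `mean_rate_hz`, `significant`, `good_fit`, `evaluable`, `condition`.
#' @export
tidy.sleeploop_plfit <- function(x, ...) {
  tibble::tibble(condition = x$condition, a = x$a, b = x$b, c = x$c,
                 r2 = x$r2, ld = x$ld, rayleigh_p = x$rayleigh_p,
                 pref_phase_deg = x$pref_phase_deg,
                 phase_category = x$phase_category,
                 n_spikes = x$n_spikes, mean_rate_hz = x$mean_rate_hz,
                 significant = x$significant, good_fit = x$good_fit,
                 evaluable = x$evaluable)
}

#' @rdname tidy.sleeploop_plfit
#' @export
glance.sleeploop_plfit <- function(x, ...) {
  tibble::tibble(ld = x$ld, r2 = x$r2, rayleigh_p = x$rayleigh_p,
                 n_spikes = x$n_spikes, evaluable = x$evaluable)
}

#' Tidy a stimulation log
#'
#' @param x a `sleeploop_stimlog` from [run_closed_loop()].
#' @param ... unused.
#' @return the per-stimulation tibble (`time_s`, `block`, `crossing_s`,
#'   `peak_s`, `delay_from_peak_s`).
#' @export
tidy.sleeploop_stimlog <- function(x, ...) x$stims

#' @rdname tidy.sleeploop_stimlog
#' @export
glance.sleeploop_stimlog <- function(x, ...) {
  isi <- diff(x$stims$time_s)
  tibble::tibble(n_stims = nrow(x$stims),
                 n_stim_blocks = sum(x$blocks$kind == "STIM"),
                 min_isi_s = if (length(isi)) min(isi) else NA_real_,
                 mode = x$protocol$mode)
}

#' Tidy a time-frequency response into long format
#'
#' @param x a `sleeploop_tfr` from [stim_locked_tfr()].
#' @param ... unused.
#' @return tibble with `freq_hz`, `time_s`, `pct_change`.
#' @export
tidy.sleeploop_tfr <- function(x, ...) {
  tibble::tibble(freq_hz = rep(x$freq_hz, times = length(x$time_s)),
                 time_s = rep(x$time_s, each = length(x$freq_hz)),
                 pct_change = as.vector(x$values))
}
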