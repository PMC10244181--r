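# Stimulation-locked analyses: matched sham events, time-frequency response,
# event probabilities and enhancement (contrast) indices, and oscillation
# co-occurrence measures.

#' Matched sham events from pause-block slow-wave peaks
#'
#' For every real stimulation, one sham event is constructed in a pause
#' block: a slow-wave peak detected in the pause block that follows the
#' stimulation's block is selected at random and offset by that
#' stimulation's own delay from its preceding peak. The sham set therefore
#' matches the stimulations in number and in phase relation to the slow-wave
#' cycle, controlling for endogenous coupling between slow-wave active
#' phases and spindles/ripples.
#'
#' @param stim_log a `sleeploop_stimlog` from [run_closed_loop()].
#' @param pause_peaks_s slow-wave positive-peak times detected inside pause
#'   blocks (seconds). Ignored by the `"random"` policy.
#' @param seed integer seed.
#' @param policy `"matched"` (default; delay-matched pause-block peaks) or
#'   `"random"`: `n_random` points drawn uniformly over the pause blocks,
#'   the simpler control used to confirm matched-sham results.
#' @param n_random number of random sham points (default 1000).
#' @return tibble with `time_s` (sham timestamp), `stim_time_s` (the matched
#'   stimulation, NA for random shams) and `source_peak_s` (the pause-block
#'   peak used, NA for random shams); sorted by `time_s`.
#' @export
generate_sham_events <- function(stim_log, pause_peaks_s, seed = 1L,
                                 policy = c("matched", "random"),
                                 n_random = 1000) {
  stopifnot(inherits(stim_log, "sleeploop_stimlog"))
  policy <- match.arg(policy)
  if (policy == "random") {
    pauses <- stim_log$blocks[stim_log$blocks$kind == "PAUSE", , drop = FALSE]
    if (nrow(pauses) == 0) stop("no pause blocks available", call. = FALSE)
    set.seed(seed)
    len <- pauses$end_s - pauses$start_s
    pick <- sample.int(nrow(pauses), n_random, replace = TRUE, prob = len)
    t_s <- pauses$start_s[pick] + stats::runif(n_random) * len[pick]
    return(tibble::tibble(time_s = sort(t_s), stim_time_s = NA_real_,
                          source_peak_s = NA_real_))
  }
  pause_peaks_s <- sort(pause_peaks_s)
  stims <- stim_log$stims
  if (nrow(stims) == 0) {
    return(tibble::tibble(time_s = numeric(), stim_time_s = numeric(),
                          source_peak_s = numeric()))
  }
  bl <- stim_log$blocks
  pause_of <- function(t) {
    i <- which(bl$kind == "PAUSE" & bl$start_s >= t)
    if (length(i)) i[1] else NA_integer_
  }
  in_pause <- vapply(pause_peaks_s, function(p) {
    any(bl$kind == "PAUSE" & bl$start_s <= p & p < bl$end_s)
  }, logical(1))
  pause_peaks_s <- pause_peaks_s[in_pause]
  if (length(pause_peaks_s) == 0) stop("no pause-block slow-wave peaks available", call. = FALSE)
  set.seed(seed)
  out <- lapply(unique(stims$block), function(b) {
    s <- stims[stims$block == b, , drop = FALSE]
    p_idx <- pause_of(bl$end_s[b] - 1e-9)
    pk <- if (!is.na(p_idx)) {
      pause_peaks_s[pause_peaks_s >= bl$start_s[p_idx] & pause_peaks_s < bl$end_s[p_idx]]
    } else numeric(0)
    if (length(pk) == 0) pk <- pause_peaks_s
    replace <- length(pk) < nrow(s)
    if (replace) {
      message("fewer pause-block peaks than stimulations; resampling with replacement")
    }
    chosen <- pk[sample.int(length(pk), nrow(s), replace = replace)]
    tibble::tibble(time_s = chosen + s$delay_from_peak_s,
                   stim_time_s = s$time_s, source_peak_s = chosen)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$time_s)
}

#' Trigger-locked time-frequency response (percent change from baseline)
#'
#' A spectrogram is computed around each trigger (5-30 Hz, 1-Hz steps) with
#' a sliding Hann-tapered window whose length is frequency dependent and
#' spans at least `min_cycles` cycles. Each trigger's spectrogram is
#' normalized as the percentage change from its own pre-trigger baseline
#' window, then averaged over triggers.
#'
#' @param x numeric signal, microvolts.
#' @param rate_hz sampling rate.
#' @param trigger_times_s trigger (stimulation or sham) timestamps.
#' @param freq_hz frequency grid, Hz (default 5:30).
#' @param t_range time grid limits relative to the trigger, seconds
#'   (default `c(-1, 2.5)`).
#' @param dt_s time-grid step (default 0.05).
#' @param baseline baseline window relative to the trigger (default
#'   `c(-1, 0)`).
#' @param min_cycles minimum cycles per analysis window (default 5).
#' @param valid_mask optional logical mask; triggers whose full window
#'   touches invalid samples are dropped.
#' @return `sleeploop_tfr` object: list with `values` (frequency x time
#'   matrix, %), `freq_hz`, `time_s`, `n_triggers`.
#' @export
stim_locked_tfr <- function(x, rate_hz, trigger_times_s, freq_hz = 5:30,
                            t_range = c(-1, 2.5), dt_s = 0.05,
                            baseline = c(-1, 0), min_cycles = 5,
                            valid_mask = NULL) {
  n <- length(x)
  tau <- seq(t_range[1], t_range[2], by = dt_s)
  max_win <- max(min_cycles / freq_hz) / 2
  ok <- trigger_times_s + t_range[1] - max_win > 0 &
    trigger_times_s + t_range[2] + max_win < n / rate_hz
  if (!is.null(valid_mask)) {
    ok <- ok & vapply(trigger_times_s, function(t) {
      i0 <- time_to_index(t + t_range[1], rate_hz, n)
      i1 <- time_to_index(t + t_range[2], rate_hz, n)
      all(valid_mask[i0:i1])
    }, logical(1))
  }
  trig <- trigger_times_s[ok]
  if (length(trig) == 0) stop("no usable triggers with full analysis context", call. = FALSE)
  base_sel <- tau >= baseline[1] & tau < baseline[2]
  nfft <- stats::nextn(n + ceiling(rate_hz * max(min_cycles / freq_hz)), 2)
  fx <- stats::fft(c(x, numeric(nfft - n)))
  acc <- matrix(0, nrow = length(freq_hz), ncol = length(tau))
  pow_at <- matrix(0, nrow = length(trig), ncol = length(tau))
  for (fi in seq_along(freq_hz)) {
    f <- freq_hz[fi]
    L <- ceiling(min_cycles / f * rate_hz)
    tt <- (seq_len(L) - (L + 1) / 2) / rate_hz
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
    kern <- w * exp(-2i * pi * f * tt) / sum(w)
    fk <- stats::fft(c(kern, numeric(nfft - L)))
    conv <- stats::fft(fx * fk, inverse = TRUE)[seq_len(n + L - 1L)] / nfft
    centered <- conv[((L + 1) %/% 2):(n + (L + 1) %/% 2 - 1L)]  # align kernel center
    pow <- Mod(centered)^2
    for (k in seq_along(trig)) {
      idx <- time_to_index(trig[k] + tau, rate_hz, n)
      pow_at[k, ] <- pow[idx]
    }
    # average across triggers first, then percent change from the average's
    # own baseline: normalizing each trigger by its noisy baseline estimate
    # would bias the null upward (E[P/B] > 1)
    avg <- colMeans(pow_at)
    base <- mean(avg[base_sel])
    acc[fi, ] <- 100 * (avg - base) / base
  }
  structure(list(values = acc, freq_hz = freq_hz, time_s = tau,
                 n_triggers = length(trig)),
            class = "sleeploop_tfr")
}

#' @export
print.sleeploop_tfr <- function(x, ...) {
  cat(sprintf("<sleeploop_tfr> %d freqs x %d times, %d trigger(s)\n",
              length(x$freq_hz), length(x$time_s), x$n_triggers))
  invisible(x)
}

#' Mean percent power change of a TFR in a frequency band and time window
#'
#' @param tfr a [stim_locked_tfr()] result.
#' @param freq_range,time_range band and window over which to average.
#' @return mean percentage change.
#' @export
tfr_band_change <- function(tfr, freq_range = c(9, 16), time_range = c(0, 2.5)) {
  fr <- tfr$freq_hz >= freq_range[1] & tfr$freq_hz <= freq_range[2]
  tr <- tfr$time_s >= time_range[1] & tfr$time_s <= time_range[2]
  mean(tfr$values[fr, tr])
}

#' Probability of detecting an event after a trigger
#'
#' Counts event peaks inside `(trigger, trigger + window_s]` over all
#' triggers. The primary probability is total detections divided by the
#' number of triggers; the fraction of triggers followed by at least one
#' event is reported alongside.
#'
#' @param event_peaks_s event peak times, seconds.
#' @param trigger_times_s trigger times, seconds.
#' @param window_s window length: 3 s for slow waves and spindles, 0.2 s
#'   for ripples.
#' @return one-row tibble: `probability` (detections per trigger),
#'   `frac_triggers_with_event`, `n_detections`, `n_triggers`.
#' @export
event_probability <- function(event_peaks_s, trigger_times_s, window_s = 3) {
  if (length(trigger_times_s) == 0) stop("no triggers supplied", call. = FALSE)
  counts <- vapply(trigger_times_s, function(t) {
    sum(event_peaks_s > t & event_peaks_s <= t + window_s)
  }, 0)
  tibble::tibble(probability = sum(counts) / length(trigger_times_s),
                 frac_triggers_with_event = mean(counts > 0),
                 n_detections = sum(counts),
                 n_triggers = length(trigger_times_s))
}

#' Normalized contrast (enhancement) index
#'
#' `(a - b) / (a + b)`, bounded in `[-1, 1]`, `NA` (excluded) when both
#' terms are zero. Vectorized.
#'
#' @param a,b non-negative rates or probabilities.
#' @return numeric contrast values.
#' @export
contrast_index <- function(a, b) {
  out <- (a - b) / (a + b)
  out[(a + b) == 0] <- NA_real_
  out
}

#' Immediate stimulation-vs-sham enhancement index
#'
#' Contrasts the probability of detecting an event after stimulations with
#' the probability after matched sham events:
#' `(P_stim - P_sham) / (P_stim + P_sham)`.
#'
#' @param p_stim,p_sham event probabilities (from [event_probability()]).
#' @return one-row tibble: `value`, `p_stim`, `p_sham`, `excluded` (TRUE
#'   when both probabilities are zero and the index is undefined).
#' @export
immediate_contrast <- function(p_stim, p_sham) {
  v <- contrast_index(p_stim, p_sham)
  tibble::tibble(value = v, p_stim = p_stim, p_sham = p_sham,
                 excluded = is.na(v))
}

#' Per-participant enhancement score
#'
#' The median of per-channel enhancement values, excluding channels whose
#' index is undefined (no detections in either condition).
#'
#' @param channel_values numeric vector of per-channel contrast indices
#'   (NA = excluded channel).
#' @return the median, or `NA` when no channel is evaluable.
#' @export
participant_enhancement_score <- function(channel_values) {
  v <- channel_values[is.finite(channel_values)]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Prolonged (1-min post-block vs pre-next-block) enhancement index
#'
#' Event rates are pooled over the first minute after each stimulation
#' block and over the last minute of each pause block (the furthest
#' equal-length period before the following stimulation block), then
#' combined in the contrast index. Requires at least one complete
#' STIM -> PAUSE -> STIM cycle.
#'
#' @param event_peaks_s event peak times, seconds.
#' @param blocks block tibble (`start_s`, `end_s`, `kind`) from a
#'   `sleeploop_stimlog`.
#' @param window_s comparison window length, seconds (default 60).
#' @return one-row tibble: `value`, `rate_post_per_min`, `rate_pre_per_min`,
#'   `n_windows`, `excluded`.
#' @export
prolonged_enhancement <- function(event_peaks_s, blocks, window_s = 60) {
  stim_i <- which(blocks$kind == "STIM")
  cycles <- stim_i[vapply(stim_i, function(i) {
    i + 2 <= nrow(blocks) && blocks$kind[i + 1] == "PAUSE" && blocks$kind[i + 2] == "STIM"
  }, logical(1))]
  if (length(cycles) == 0) stop("need at least one complete STIM->PAUSE->STIM cycle", call. = FALSE)
  n_post <- n_pre <- 0; t_tot <- 0
  for (i in cycles) {
    post <- c(blocks$end_s[i], blocks$end_s[i] + window_s)
    pre <- c(blocks$start_s[i + 2] - window_s, blocks$start_s[i + 2])
    n_post <- n_post + sum(event_peaks_s >= post[1] & event_peaks_s < post[2])
    n_pre <- n_pre + sum(event_peaks_s >= pre[1] & event_peaks_s < pre[2])
    t_tot <- t_tot + window_s
  }
  rate_post <- n_post / (t_tot / 60); rate_pre <- n_pre / (t_tot / 60)
  v <- contrast_index(rate_post, rate_pre)
  tibble::tibble(value = v, rate_post_per_min = rate_post,
                 rate_pre_per_min = rate_pre, n_windows = length(cycles),
                 excluded = is.na(v))
}

#' Slow-wave / spindle sequences
#'
#' Pairs each spindle peak with the nearest preceding slow-wave positive
#' peak when the spindle follows it by at most `max_delay_s` (strictly
#' positive delay); each spindle joins at most one sequence.
#'
#' @param slow_waves slow-wave event tibble (needs `peak_s`).
#' @param spindles spindle event tibble (needs `peak_s`, optionally
#'   `is_fast`).
#' @param max_delay_s coupling window, seconds (default 1.5).
#' @param fast_only restrict to fast (> 11 Hz) spindles (default FALSE; the
#'   co-occurrence analyses typically use TRUE).
#' @return tibble: `sw_peak_s`, `spindle_peak_s`, `delay_s`.
#' @export
sw_spindle_sequences <- function(slow_waves, spindles, max_delay_s = 1.5,
                                 fast_only = FALSE) {
  sp <- spindles
  if (fast_only && "is_fast" %in% names(sp)) sp <- sp[!is.na(sp$is_fast) & sp$is_fast, ]
  swp <- sort(slow_waves$peak_s)
  if (length(swp) == 0 || nrow(sp) == 0) {
    return(tibble::tibble(sw_peak_s = numeric(), spindle_peak_s = numeric(),
                          delay_s = numeric()))
  }
  rows <- lapply(sp$peak_s, function(p) {
    prev <- swp[swp < p]
    if (!length(prev)) return(NULL)
    d <- p - prev[length(prev)]
    if (d > max_delay_s) return(NULL)
    tibble::tibble(sw_peak_s = prev[length(prev)], spindle_peak_s = p, delay_s = d)
  })
  dplyr::bind_rows(rows)
}

#' MTL ripple / neocortical slow-wave couples and per-window incidence
#'
#' A couple is a ripple peak within `window_ms` of a slow-wave positive
#' peak (absolute distance by default, the convention for "away from";
#' `signed = TRUE` requires the ripple to precede the peak). Each ripple
#' joins at most one couple (nearest peak). Incidence is computed per
#' evaluation window; windows containing 10 or fewer slow waves are
#' excluded.
#'
#' @param ripples ripple event tibble (needs `peak_s`).
#' @param slow_waves slow-wave event tibble on the paired neocortical
#'   channel (needs `peak_s`).
#' @param windows tibble of evaluation windows (`start_s`, `end_s`).
#' @param window_ms coupling distance bounds, ms (default `c(50, 400)`).
#' @param signed require ripple to precede the slow-wave peak.
#' @param min_sw minimum slow waves per evaluated window (default 10,
#'   exclusive).
#' @return list with `couples` (tibble: `ripple_peak_s`, `sw_peak_s`,
#'   `delta_ms`) and `windows` (tibble: `start_s`, `end_s`, `n_sw`,
#'   `n_couples`, `incidence_per_min`, `excluded`).
#' @export
ripple_sw_cooccurrence <- function(ripples, slow_waves, windows,
                                   window_ms = c(50, 400), signed = FALSE,
                                   min_sw = 10) {
  swp <- sort(slow_waves$peak_s)
  rows <- lapply(ripples$peak_s, function(r) {
    d <- swp - r                      # positive: peak after ripple
    cand <- if (signed) d else abs(d)
    ok <- which(cand >= window_ms[1] / 1000 & cand <= window_ms[2] / 1000)
    if (!length(ok)) return(NULL)
    j <- ok[which.min(cand[ok])]
    tibble::tibble(ripple_peak_s = r, sw_peak_s = swp[j], delta_ms = d[j] * 1000)
  })
  couples <- dplyr::bind_rows(rows)
  if (nrow(couples) == 0) {
    couples <- tibble::tibble(ripple_peak_s = numeric(), sw_peak_s = numeric(),
                              delta_ms = numeric())
  }
  windows <- tibble::as_tibble(windows)
  win <- purrr::pmap(windows[, c("start_s", "end_s")], function(start_s, end_s) {
    n_sw <- sum(swp >= start_s & swp < end_s)
    n_c <- sum(couples$ripple_peak_s >= start_s & couples$ripple_peak_s < end_s)
    excluded <- n_sw <= min_sw
    tibble::tibble(start_s = start_s, end_s = end_s, n_sw = n_sw,
                   n_couples = n_c,
                   incidence_per_min = if (excluded) NA_real_ else n_c / ((end_s - start_s) / 60),
                   excluded = excluded)
  })
  list(couples = couples, windows = dplyr::bind_rows(win))
}

#' Ripple-coupled slow-wave/spindle triples
#'
#' A triple is an MTL ripple peak preceding the slow wave of a slow-wave /
#' spindle sequence by 50-400 ms (signed direction).
#'
#' @param ripples ripple event tibble (needs `peak_s`).
#' @param sequences output of [sw_spindle_sequences()].
#' @param window_ms signed precedence bounds, ms (default `c(50, 400)`).
#' @return tibble: `ripple_peak_s`, `sw_peak_s`, `spindle_peak_s`.
#' @export
triple_cooccurrence <- function(ripples, sequences, window_ms = c(50, 400)) {
  if (nrow(sequences) == 0 || nrow(ripples) == 0) {
    return(tibble::tibble(ripple_peak_s = numeric(), sw_peak_s = numeric(),
                          spindle_peak_s = numeric()))
  }
  rows <- lapply(seq_len(nrow(sequences)), function(i) {
    d <- sequences$sw_peak_s[i] - ripples$peak_s     # ripple precedes peak
    ok <- which(d >= window_ms[1] / 1000 & d <= window_ms[2] / 1000)
    if (!length(ok)) return(NULL)
    j <- ok[which.min(d[ok])]
    tibble::tibble(ripple_peak_s = ripples$peak_s[j],
                   sw_peak_s = sequences$sw_peak_s[i],
                   spindle_peak_s = sequences$spindle_peak_s[i])
  })
  out <- dplyr::bind_rows(rows)
  # one triple per ripple: keep the tightest sequence for a shared ripple
  if (nrow(out) > 1) {
    out <- dplyr::slice_min(dplyr::group_by(out, .data$ripple_peak_s),
                            .data$sw_peak_s - .data$ripple_peak_s,
                            n = 1, with_ties = FALSE)
    out <- dplyr::arrange(dplyr::ungroup(out), .data$ripple_peak_s)
  }
  out
}
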