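# Single-event detectors for slow waves, sleep spindles and MTL ripples.
# All detectors consume one channel's signal plus a logical mask of valid
# NREM samples, and return tidy event tibbles with times in seconds from
# recording start; intervals are half-open [onset, offset).

empty_events <- function(kind) {
  tibble::tibble(kind = character(), onset_s = numeric(), offset_s = numeric(),
                 peak_s = numeric(), trough_s = numeric(), amp_uv = numeric(),
                 peak_freq_hz = numeric(), is_fast = logical())[0, ]
}

#' Detect slow waves on one channel
#'
#' The signal is band-passed 0.16-1.25 Hz with a two-pass (zero-phase) FIR
#' filter whose order is three cycles of the low cutoff (`3 * rate / 0.16`
#' taps). Candidates are the spans between successive negative-to-positive
#' zero crossings of the filtered signal that contain a positive peak
#' (inactive/OFF phase) followed by a trough (active/ON phase) and last
#' 0.8-2 s. Candidates whose peak-to-trough amplitude reaches the 75th
#' percentile of candidate amplitudes (linear-interpolation percentile) are
#' retained as slow waves.
#'
#' @param x numeric signal, microvolts.
#' @param rate_hz sampling rate.
#' @param valid_mask logical per-sample valid-NREM mask (default all TRUE);
#'   candidates must lie entirely inside valid samples.
#' @param amp_percentile amplitude criterion quantile (default 0.75).
#' @param amplitude_criterion apply the percentile criterion (default TRUE).
#'   With FALSE all duration-qualified candidates are returned — the
#'   population used e.g. as reference peaks by [audit_stim_timing()].
#' @return tibble with columns `kind`, `onset_s`, `offset_s`, `peak_s`
#'   (positive peak, OFF), `trough_s` (ON), `amp_uv` (peak-to-trough),
#'   `peak_freq_hz`, `is_fast` (NA for slow waves).
#' @export
detect_slow_waves <- function(x, rate_hz, valid_mask = NULL,
                              amp_percentile = 0.75, amplitude_criterion = TRUE) {
  n <- length(x)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  order <- round(3 * rate_hz / 0.16)
  if (n <= order / 2) stop("signal shorter than one filter order", call. = FALSE)
  filt <- fir_bandpass(x, rate_hz, 0.16, 1.25, order)
  up <- which(filt[-n] < 0 & filt[-1] >= 0)
  if (length(up) < 2L) return(empty_events("slow_wave"))
  out <- list()
  for (i in seq_len(length(up) - 1L)) {
    i0 <- up[i] + 1L; i1 <- up[i + 1L]
    dur <- (i1 - i0 + 1L) / rate_hz
    if (dur < 0.8 || dur > 2) next
    if (!all(valid_mask[i0:i1])) next
    seg <- filt[i0:i1]
    ipk <- which.max(seg); itr <- which.min(seg)
    if (seg[ipk] <= 0 || seg[itr] >= 0 || itr <= ipk) next
    out[[length(out) + 1L]] <- c(i0, i1, i0 + ipk - 1L, i0 + itr - 1L, seg[ipk] - seg[itr])
  }
  if (!length(out)) return(empty_events("slow_wave"))
  m <- do.call(rbind, out)
  keep <- if (amplitude_criterion) {
    # 0.5% relative tolerance keeps amplitude ties at the percentile together
    m[, 5] >= stats::quantile(m[, 5], amp_percentile, type = 7) * (1 - 5e-3)
  } else rep(TRUE, nrow(m))
  m <- m[keep, , drop = FALSE]
  tibble::tibble(kind = "slow_wave",
                 onset_s = (m[, 1] - 1L) / rate_hz,
                 offset_s = m[, 2] / rate_hz,
                 peak_s = (m[, 3] - 1L) / rate_hz,
                 trough_s = (m[, 4] - 1L) / rate_hz,
                 amp_uv = m[, 5],
                 peak_freq_hz = 1 / ((m[, 2] - m[, 1] + 1L) / rate_hz),
                 is_fast = NA)
}

#' Qualify a channel for spindle detection against a 1/f spectral model
#'
#' NREM sigma-band (9-16 Hz) power is compared with a fitted `1/f^a` model.
#' The log spectrum is estimated over non-overlapping 10-s valid-NREM
#' epochs; the model is fitted to the epoch-mean log spectrum over 2-40 Hz
#' excluding the sigma band. The per-epoch maximal sigma-band residual is
#' compared with the per-epoch maximal residual over an equal-width control
#' band (17-24 Hz) by a one-sided unpaired t-test; the channel qualifies
#' when the excess is significant at `p_threshold`.
#'
#' @param x numeric signal, microvolts.
#' @param rate_hz sampling rate.
#' @param valid_mask logical valid-NREM mask.
#' @param epoch_s spectral epoch length, seconds (default 10).
#' @param min_epochs minimum epochs to evaluate (default 20).
#' @param p_threshold significance level (default 0.001).
#' @return one-row tibble: `n_epochs`, `sigma_excess_log10`, `p_value`,
#'   `qualified`, `evaluable`.
#' @export
qualify_spindle_channel <- function(x, rate_hz, valid_mask = NULL, epoch_s = 10,
                                    min_epochs = 20, p_threshold = 0.001) {
  n <- length(x)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  nseg <- floor(epoch_s * rate_hz)
  runs <- logical_runs(valid_mask)
  segs <- list()
  for (r in seq_len(nrow(runs))) {
    i0 <- runs[r, 1]
    while (i0 + nseg - 1L <= runs[r, 2]) {
      segs[[length(segs) + 1L]] <- x[i0:(i0 + nseg - 1L)]
      i0 <- i0 + nseg
    }
  }
  if (length(segs) < min_epochs) {
    return(tibble::tibble(n_epochs = length(segs), sigma_excess_log10 = NA_real_,
                          p_value = NA_real_, qualified = NA, evaluable = FALSE))
  }
  freqs <- seq(0, rate_hz / 2, by = 1 / epoch_s)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  spec <- vapply(segs, function(s) {
    s <- (s - mean(s)) * w
    (Mod(stats::fft(s))^2 / (sum(w^2) * rate_hz))[seq_along(freqs)]
  }, numeric(length(freqs)))
  logspec <- log10(spec + 1e-20)
  mean_log <- rowMeans(logspec)
  fit_sel <- freqs >= 2 & freqs <= min(40, rate_hz / 2 - 1) & !(freqs >= 9 & freqs <= 16)
  coef <- stats::lm.fit(cbind(1, log10(freqs[fit_sel])), mean_log[fit_sel])$coefficients
  model <- coef[1] + coef[2] * log10(pmax(freqs, 1e-6))
  resid <- logspec - model  # per-frequency, per-epoch residual from 1/f
  sigma_sel <- freqs >= 9 & freqs <= 16
  ctrl_sel <- freqs >= 17 & freqs <= 24
  sig_max <- apply(resid[sigma_sel, , drop = FALSE], 2, max)
  ctrl_max <- apply(resid[ctrl_sel, , drop = FALSE], 2, max)
  tt <- stats::t.test(sig_max, ctrl_max, alternative = "greater", var.equal = FALSE)
  tibble::tibble(n_epochs = length(segs),
                 sigma_excess_log10 = mean(sig_max) - mean(ctrl_max),
                 p_value = tt$p.value,
                 qualified = tt$p.value < p_threshold,
                 evaluable = TRUE)
}

#' Detect sleep spindles on one (qualified) channel
#'
#' The signal is band-passed 9-16 Hz (zero-phase fourth-order Butterworth)
#' and the instantaneous (Hilbert) amplitude thresholded at the mean + 3 SD
#' of the amplitude over valid-NREM samples; event boundaries extend to the
#' mean + 1 SD crossing, events lasting 0.5-2 s are kept, and detections
#' within 1 s of each other are merged. Detections coinciding with 20-30 Hz
#' control events above mean + 5 SD are vetoed (broadband/sharp transients).
#' The event peak is the largest positive peak of the filtered signal; peak
#' frequency is estimated from the mean inter-peak interval, and spindles
#' with peak frequency above 11 Hz are flagged fast.
#'
#' @param x numeric signal, microvolts.
#' @param rate_hz sampling rate.
#' @param valid_mask logical valid-NREM mask.
#' @param detect_sd,bound_sd detection and boundary thresholds, SD units
#'   (defaults 3 and 1).
#' @param merge_gap_s merge gap, seconds (default 1).
#' @param veto_sd control-band veto threshold, SD units (default 5).
#' @return event tibble as in [detect_slow_waves()]; `is_fast` is TRUE for
#'   peak frequency > 11 Hz.
#' @export
detect_spindles <- function(x, rate_hz, valid_mask = NULL, detect_sd = 3,
                            bound_sd = 1, merge_gap_s = 1, veto_sd = 5) {
  n <- length(x)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  if (stats::sd(x[valid_mask]) < 1e-12) stop("zero-variance signal", call. = FALSE)
  filt <- butter_bandpass(x, rate_hz, 9, 16, order = 4L)
  env <- Mod(analytic_signal(filt))
  mu <- mean(env[valid_mask]); sdv <- stats::sd(env[valid_mask])
  hi <- env > mu + detect_sd * sdv & valid_mask
  lo <- env > mu + bound_sd * sdv & valid_mask
  cand <- logical_runs(hi)
  if (nrow(cand) == 0) return(empty_events("spindle"))
  lo_runs <- logical_runs(lo)
  # extend each detection to its surrounding boundary-threshold run
  ext <- t(apply(cand, 1, function(r) {
    k <- which(lo_runs[, 1] <= r[1] & lo_runs[, 2] >= r[2])
    if (length(k)) lo_runs[k[1], ] else r
  }))
  ext <- unique(ext)
  dur <- (ext[, 2] - ext[, 1] + 1L) / rate_hz
  ext <- ext[dur >= 0.5 & dur <= 2, , drop = FALSE]
  if (nrow(ext) == 0) return(empty_events("spindle"))
  ext <- ext[order(ext[, 1]), , drop = FALSE]
  merged <- list(ext[1, ])
  if (nrow(ext) > 1) {
    for (i in 2:nrow(ext)) {
      last <- merged[[length(merged)]]
      if ((ext[i, 1] - last[2]) / rate_hz < merge_gap_s) {
        merged[[length(merged)]][2] <- max(last[2], ext[i, 2])
      } else merged[[length(merged) + 1L]] <- ext[i, ]
    }
  }
  m <- do.call(rbind, merged)
  # 20-30 Hz control events (broadband sharp transients) veto
  veto <- matrix(numeric(0), ncol = 2)
  if (rate_hz > 60) {
    ctrl <- butter_bandpass(x, rate_hz, 20, 30, order = 4L)
    cenv <- Mod(analytic_signal(ctrl))
    cmu <- mean(cenv[valid_mask]); csd <- stats::sd(cenv[valid_mask])
    veto <- logical_runs(cenv > cmu + veto_sd * csd & valid_mask)
  }
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any(veto[, 1] <= m[i, 2] & veto[, 2] >= m[i, 1])
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) return(empty_events("spindle"))
  rows <- lapply(seq_len(nrow(m)), function(i) {
    idx <- m[i, 1]:m[i, 2]
    seg <- filt[idx]
    pk <- local_maxima(seg)
    if (length(pk) == 0) pk <- which.max(seg)
    peak_i <- idx[pk[which.max(seg[pk])]]
    pf <- if (length(pk) >= 2) 1 / (mean(diff(pk)) / rate_hz) else NA_real_
    tibble::tibble(kind = "spindle",
                   onset_s = (m[i, 1] - 1L) / rate_hz, offset_s = m[i, 2] / rate_hz,
                   peak_s = (peak_i - 1L) / rate_hz, trough_s = NA_real_,
                   amp_uv = max(env[idx]), peak_freq_hz = pf,
                   is_fast = !is.na(pf) && pf > 11)
  })
  dplyr::bind_rows(rows)
}

#' Bipolar re-reference: gray-matter contact minus white-matter contact
#'
#' @param gray,white numeric signals of equal length (same rate).
#' @param rate_gray,rate_white optional rates; must match when given.
#' @return numeric vector `gray - white`.
#' @export
bipolar_reference <- function(gray, white, rate_gray = NULL, rate_white = NULL) {
  if (!is.null(rate_gray) && !is.null(rate_white) && rate_gray != rate_white) {
    stop("sampling rates differ between contacts", call. = FALSE)
  }
  if (length(gray) != length(white)) stop("signals differ in length", call. = FALSE)
  gray - white
}

#' Detect MTL ripples on a bipolar-referenced channel
#'
#' The signal is band-passed 80-100 Hz (two-pass FIR, order three cycles of
#' 80 Hz), and its RMS computed with a 20-ms moving average. The amplitude
#' criterion is the 99th percentile of valid-NREM RMS values; runs above it
#' lasting at least 38 ms (~3 cycles at 80 Hz) are putative ripples. To
#' reject sharp broadband events, the corresponding raw segment — smoothed
#' with a one-pass 3-point moving average — must contain at least three
#' discrete local maxima or three local minima. A channel qualifies for
#' downstream analyses when at least `min_baseline_count` ripples are
#' detected within the designated baseline period.
#'
#' @param x numeric bipolar signal, microvolts.
#' @param rate_hz sampling rate (> 200).
#' @param valid_mask logical valid-NREM mask.
#' @param baseline_window two-element numeric, the pre-sleep baseline period
#'   `(start_s, end_s)` used for channel qualification.
#' @param rms_percentile amplitude-criterion quantile (default 0.99).
#' @param min_dur_s minimum above-threshold duration (default 0.038).
#' @param min_baseline_count detections required in baseline to qualify the
#'   channel (default 20).
#' @return list with `events` (tibble as in [detect_slow_waves()]),
#'   `qualified` (logical), `n_baseline` (count in the baseline window).
#' @export
detect_ripples <- function(x, rate_hz, valid_mask = NULL,
                           baseline_window = c(0, Inf), rms_percentile = 0.99,
                           min_dur_s = 0.038, min_baseline_count = 20) {
  n <- length(x)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  if (rate_hz <= 200) stop("sampling rate too low for 80-100 Hz ripple detection", call. = FALSE)
  filt <- fir_bandpass(x, rate_hz, 80, 100, round(3 * rate_hz / 80))
  rms <- sqrt(moving_average(filt^2, round(0.02 * rate_hz)))
  thr <- stats::quantile(rms[valid_mask], rms_percentile, type = 7)
  runs <- logical_runs(rms > thr & valid_mask)
  events <- empty_events("ripple")
  if (nrow(runs) > 0) {
    # the 20-ms moving average smears each burst by half a window per side;
    # shrink runs accordingly so the duration criterion measures the burst,
    # not the smoothing kernel, and peak counting stays inside it
    half <- round(0.01 * rate_hz)
    runs[, 1] <- runs[, 1] + half
    runs[, 2] <- runs[, 2] - half
    runs <- runs[runs[, 2] > runs[, 1], , drop = FALSE]
    dur <- (runs[, 2] - runs[, 1] + 1L) / rate_hz
    runs <- runs[dur >= min_dur_s, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(runs))) {
      idx <- runs[i, 1]:runs[i, 2]
      raw_s <- moving_average(x[idx], 3L)
      if (length(local_maxima(raw_s)) < 3 && length(local_minima(raw_s)) < 3) next
      seg <- filt[idx]
      pk <- local_maxima(seg)
      peak_i <- if (length(pk)) idx[pk[which.max(seg[pk])]] else idx[which.max(seg)]
      pf <- if (length(pk) >= 2) 1 / (mean(diff(pk)) / rate_hz) else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "ripple", onset_s = (runs[i, 1] - 1L) / rate_hz,
        offset_s = runs[i, 2] / rate_hz, peak_s = (peak_i - 1L) / rate_hz,
        trough_s = NA_real_, amp_uv = max(rms[idx]), peak_freq_hz = pf,
        is_fast = NA)
    }
    if (length(rows)) events <- dplyr::bind_rows(rows)
  }
  n_base <- sum(events$peak_s >= baseline_window[1] & events$peak_s < baseline_window[2])
  list(events = events,
       qualified = n_base >= min_baseline_count,
       n_baseline = n_base)
}

#' Minimum ripple duration implied by a cycle criterion
#'
#' The shortest event that can contain `n_cycles` cycles at `freq_hz`,
#' rounded up to the next millisecond.
#'
#' @param n_cycles number of cycles (default 3).
#' @param freq_hz lower edge of the ripple band (default 80).
#' @return duration in milliseconds.
#' @examples
#' ripple_min_duration_ms()  # 38
#' @export
ripple_min_duration_ms <- function(n_cycles = 3, freq_hz = 80) {
  ceiling(n_cycles / freq_hz * 1000)
}
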