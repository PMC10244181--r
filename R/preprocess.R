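#' Remove 60-Hz line noise and its harmonics
#'
#' Applies zero-phase 2-Hz-wide band-stop filters centered at 60 Hz and every
#' harmonic below the Nyquist frequency. Passband gain is ~1 (second-order
#' Butterworth stop bands applied forward and backward).
#'
#' @param recording a [new_recording()] object.
#' @param base_hz mains frequency (default 60).
#' @return the recording with filtered samples.
#' @export
remove_line_noise <- function(recording, base_hz = 60) {
  ny <- recording$rate_hz / 2
  harmonics <- base_hz * seq_len(floor((ny - 1.5) / base_hz))
  for (f0 in harmonics) {
    for (ch in seq_len(nrow(recording$samples))) {
      recording$samples[ch, ] <-
        butter_bandstop(recording$samples[ch, ], recording$rate_hz, f0 - 1, f0 + 1)
    }
  }
  recording
}

#' Detect interictal epileptiform discharges (IEDs) on one channel
#'
#' Each NREM sample is z-scored (per channel, over valid NREM samples) on
#' three features: absolute amplitude, gradient (difference of adjacent
#' samples), and the envelope (Hilbert magnitude) of the high-pass-filtered
#' signal. A sample is flagged when the envelope z exceeds `threshold_sd`,
#' or both amplitude and gradient z do. Contiguous flagged runs lasting
#' 70 ms or more are rejected as slow artifacts rather than discharges;
#' detections closer than 50 ms are merged.
#'
#' @param x numeric signal vector, microvolts.
#' @param rate_hz sampling rate.
#' @param nrem_mask logical per-sample NREM/valid mask (default all TRUE).
#' @param threshold_sd detection threshold in SD units (default 5).
#' @param hp_hz high-pass cutoff for the envelope feature. Default 250 Hz;
#'   automatically lowered to `0.4 * rate_hz` for recordings sampled below
#'   625 Hz, where 250 Hz is not below Nyquist.
#' @param robust use median/MAD instead of mean/SD for the z-scores.
#' @return tibble with columns `onset_s`, `offset_s`, `peak_s`, `kind`
#'   (`"ied"`).
#' @export
detect_ieds <- function(x, rate_hz, nrem_mask = NULL, threshold_sd = 5,
                        hp_hz = 250, robust = FALSE) {
  n <- length(x)
  if (is.null(nrem_mask)) nrem_mask <- rep(TRUE, n)
  stopifnot(length(nrem_mask) == n)
  if (stats::sd(x[nrem_mask]) < 1e-12) {
    stop("degenerate normalization: channel has zero variance over NREM", call. = FALSE)
  }
  hp_hz <- min(hp_hz, 0.4 * rate_hz)
  zfun <- if (robust) {
    function(v) (v - stats::median(v[nrem_mask])) / (stats::mad(v[nrem_mask]) + 1e-12)
  } else {
    function(v) (v - mean(v[nrem_mask])) / (stats::sd(v[nrem_mask]) + 1e-12)
  }
  z_amp <- zfun(abs(x))
  z_grad <- zfun(abs(c(0, diff(x))))
  env <- Mod(analytic_signal(butter_highpass(x, rate_hz, hp_hz, order = 4L)))
  z_env <- zfun(env)
  # flag the union of the three features; the amplitude/gradient conjunction
  # is checked per event (the amplitude extremum and the steepest gradient of
  # one transient are a few ms apart, never the same sample)
  hit_env <- z_env > threshold_sd
  hit_amp <- z_amp > threshold_sd
  hit_grad <- z_grad > threshold_sd
  flagged <- nrem_mask & (hit_env | hit_amp | hit_grad)
  runs <- logical_runs(flagged)
  if (nrow(runs) == 0) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          peak_s = numeric(), kind = character()))
  }
  # merge runs separated by < 50 ms
  gap <- 0.05 * rate_hz
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[i, 1] - last[2] < gap) {
        merged[[length(merged)]][2] <- runs[i, 2]
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  # envelope detections carry no duration cap; the amplitude/gradient
  # conjunction must be briefer than 70 ms (slow artifacts otherwise)
  dur <- (m[, 2] - m[, 1] + 1L) / rate_hz
  ok <- vapply(seq_len(nrow(m)), function(i) {
    idx <- m[i, 1]:m[i, 2]
    any(hit_env[idx]) ||
      (any(hit_amp[idx]) && any(hit_grad[idx]) && dur[i] < 0.07)
  }, logical(1))
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          peak_s = numeric(), kind = character()))
  }
  peak <- vapply(seq_len(nrow(m)), function(i) {
    idx <- m[i, 1]:m[i, 2]
    idx[which.max(abs(x[idx]))]
  }, 0L)
  tibble::tibble(onset_s = (m[, 1] - 1L) / rate_hz,
                 offset_s = m[, 2] / rate_hz,
                 peak_s = (peak - 1L) / rate_hz,
                 kind = "ied")
}

#' Build a per-channel validity mask from IED detections
#'
#' Marks invalid the 500 ms preceding and following every IED, flags for
#' exclusion channels whose IED rate exceeds `max_rate_per_min` over the
#' analyzed (NREM) time, and flags for review channels whose kurtosis or
#' skewness deviates from same-electrode channels by more than
#' `stat_z_bound` z-units (review flags do not auto-exclude).
#'
#' @param recording a [new_recording()] object.
#' @param ied_events tibble of IED detections with columns `channel`,
#'   `onset_s`, `offset_s` (e.g. [detect_ieds()] results bound per channel).
#' @param nrem_mask logical per-sample mask of analyzed time (default all).
#' @param pad_s exclusion padding around each IED, seconds (default 0.5).
#' @param max_rate_per_min exclusion threshold on IED rate (default 5).
#' @param stat_z_bound review threshold on kurtosis/skewness deviation.
#' @return list with `mask` (channels x samples logical matrix; TRUE =
#'   analyzable) and `channels` (tibble: `label`, `ied_rate_per_min`,
#'   `excluded`, `review`).
#' @export
build_validity_mask <- function(recording, ied_events, nrem_mask = NULL,
                                pad_s = 0.5, max_rate_per_min = 5,
                                stat_z_bound = 3) {
  n <- ncol(recording$samples)
  if (n == 0) stop("empty recording", call. = FALSE)
  rate <- recording$rate_hz
  if (is.null(nrem_mask)) nrem_mask <- rep(TRUE, n)
  labels <- recording$channels$label
  mask <- matrix(TRUE, nrow = length(labels), ncol = n, dimnames = list(labels, NULL))
  ied_events <- tibble::as_tibble(ied_events)
  rates <- numeric(length(labels))
  minutes <- sum(nrem_mask) / rate / 60
  for (i in seq_along(labels)) {
    ev <- ied_events[ied_events$channel == labels[i], , drop = FALSE]
    rates[i] <- nrow(ev) / minutes
    for (k in seq_len(nrow(ev))) {
      i0 <- time_to_index(ev$onset_s[k] - pad_s, rate, n)
      i1 <- time_to_index(ev$offset_s[k] + pad_s, rate, n)
      mask[i, i0:i1] <- FALSE
    }
  }
  kurt <- apply(recording$samples, 1, function(v) mean((v - mean(v))^4) / stats::var(v)^2)
  skew <- apply(recording$samples, 1, function(v) mean((v - mean(v))^3) / stats::sd(v)^3)
  review <- rep(FALSE, length(labels))
  for (el in unique(recording$channels$electrode)) {
    grp <- which(recording$channels$electrode == el)
    if (length(grp) >= 3) {
      zk <- abs(kurt[grp] - mean(kurt[grp])) / (stats::sd(kurt[grp]) + 1e-12)
      zs <- abs(skew[grp] - mean(skew[grp])) / (stats::sd(skew[grp]) + 1e-12)
      review[grp] <- zk > stat_z_bound | zs > stat_z_bound
    }
  }
  list(mask = mask,
       channels = tibble::tibble(label = labels,
                                 ied_rate_per_min = rates,
                                 excluded = rates > max_rate_per_min,
                                 review = review))
}
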