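#' Stimulation protocol parameters
#'
#' Parameter set for the simulated real-time closed-loop controller. The
#' defaults mirror the study protocol: slow-wave detection by an adaptive
#' positive-going threshold crossing of an online 0.5-4 Hz 50th-order FIR
#' filtered probe signal (initial threshold 80 uV, updated every 400 s to
#' the median amplitude of slow waves detected in the trailing window),
#' stimulation triggered with a delay (400 ms fixed, or adaptive from mean
#' peak-to-trough times), detection suspended for 3 s after each pulse
#' train, and 5-min stimulation blocks interleaved with 5-min pauses. Pulse
#' trains are five 100-us pulses at 100 Hz at 0.5-1.5 mA.
#'
#' @param mode `"sync"` (phase-targeted) or `"mixed"` (phase-agnostic jitter
#'   with the identical lockout and block structure).
#' @param initial_threshold_uv,threshold_update_period_s adaptive-threshold
#'   settings.
#' @param initial_delay_ms,delay_mode trigger delay and whether it adapts
#'   (`"fixed"` or `"adaptive"`; adaptive delays are bounded to 80-600 ms).
#' @param lockout_s post-stimulation detection suspension (default 3).
#' @param block_s,pause_s,n_blocks stimulation/pause block lengths (s) and
#'   number of stimulation blocks (`Inf` = as many as fit).
#' @param fir_order online FIR band-pass order (default 50).
#' @param n_pulses,pulse_freq_hz,pulse_width_us,current_ma pulse-train shape.
#' @param contact_area_cm2 stimulating contact surface area.
#' @return a named list of class `sleeploop_protocol`.
#' @export
stim_protocol <- function(mode = c("sync", "mixed"),
                          initial_threshold_uv = 80,
                          threshold_update_period_s = 400,
                          initial_delay_ms = 400,
                          delay_mode = c("fixed", "adaptive"),
                          lockout_s = 3,
                          block_s = 300, pause_s = 300, n_blocks = Inf,
                          fir_order = 50,
                          n_pulses = 5, pulse_freq_hz = 100,
                          pulse_width_us = 100, current_ma = 1.5,
                          contact_area_cm2 = 0.06) {
  mode <- match.arg(mode)
  delay_mode <- match.arg(delay_mode)
  stopifnot(lockout_s > 0, block_s > 0, pause_s > 0, initial_delay_ms >= 0)
  if (current_ma < 0.5 || current_ma > 1.5) {
    stop("current_ma outside the tested 0.5-1.5 mA range", call. = FALSE)
  }
  p <- as.list(environment())
  class(p) <- "sleeploop_protocol"
  p
}

#' Simulate the real-time closed-loop slow-wave-triggered controller
#'
#' Replays a probe-channel signal through a causal simulation of the online
#' controller: the stream is FIR band-passed 0.5-4 Hz (timestamps corrected
#' for the filter's known symmetric group delay of `fir_order/2` samples),
#' and every positive-going crossing of the adaptive threshold counts as an
#' online slow-wave detection. During stimulation blocks each detection
#' triggers a stimulation at the crossing time plus the current delay
#' (`sync`), or plus a uniform jitter over the recent inter-detection cycle
#' (`mixed`); detection resumes `lockout_s` after each stimulation. Every
#' `threshold_update_period_s` the threshold is set to the median
#' positive-peak amplitude of the slow waves detected in the trailing
#' window, and (in adaptive delay mode) the delay to the mean
#' peak-to-trough time, bounded to 80-600 ms.
#'
#' @param x probe signal, microvolts.
#' @param rate_hz sampling rate of the stream.
#' @param protocol a [stim_protocol()].
#' @param seed integer seed (used by the mixed-mode jitter).
#' @return a `sleeploop_stimlog`: list with
#'   `stims` (tibble: `time_s`, `block`, `crossing_s`, `peak_s`,
#'   `delay_from_peak_s`), `detections` (tibble: `crossing_s`, `peak_s`,
#'   `amp_uv`, `peak_to_trough_s`), `blocks` (tibble: `start_s`, `end_s`,
#'   `kind`), `threshold_trace` and `delay_trace` (tibbles of `time_s`,
#'   value), `protocol`, `rate_hz`.
#' @export
run_closed_loop <- function(x, rate_hz, protocol = stim_protocol(), seed = 1L) {
  stopifnot(inherits(protocol, "sleeploop_protocol"))
  if (rate_hz <= 8) stop("stream rate incompatible with the 0.5-4 Hz online filter", call. = FALSE)
  set.seed(seed)
  n <- length(x)
  dur <- n / rate_hz
  b <- signal::fir1(protocol$fir_order, c(0.5, 4) / (rate_hz / 2), type = "pass")
  filt <- as.numeric(stats::filter(c(x, numeric(protocol$fir_order)), b, method = "convolution",
                                   sides = 1))
  filt[is.na(filt)] <- 0
  gd <- protocol$fir_order / 2  # symmetric FIR group delay, samples
  # filt[i] estimates the band signal at sample i - gd
  t_of <- function(i) (i - 1L - gd) / rate_hz

  # block structure
  blocks <- list(); t0 <- 0; k <- 0L
  while (t0 < dur) {
    if (k < protocol$n_blocks) {
      k <- k + 1L
      blocks[[length(blocks) + 1L]] <- c(t0, min(t0 + protocol$block_s, dur), 1)
      t0 <- t0 + protocol$block_s
      if (t0 < dur) {
        blocks[[length(blocks) + 1L]] <- c(t0, min(t0 + protocol$pause_s, dur), 0)
        t0 <- t0 + protocol$pause_s
      }
    } else {
      blocks[[length(blocks) + 1L]] <- c(t0, dur, 0)
      t0 <- dur
    }
  }
  bl <- do.call(rbind, blocks)
  blocks_tbl <- tibble::tibble(start_s = bl[, 1], end_s = bl[, 2],
                               kind = ifelse(bl[, 3] == 1, "STIM", "PAUSE"))
  stim_block_of <- function(t) {
    i <- which(bl[, 1] <= t & t < bl[, 2])
    if (length(i) && bl[i[1], 3] == 1) i[1] else NA_integer_
  }

  thr <- protocol$initial_threshold_uv
  delay_s <- protocol$initial_delay_ms / 1000
  det_cross <- det_peak <- det_amp <- det_p2t <- numeric(0)
  stim_time <- stim_cross <- stim_peak <- numeric(0)
  stim_block <- integer(0)
  thr_trace <- list(c(0, thr)); delay_trace <- list(c(0, delay_s))
  next_update <- protocol$threshold_update_period_s
  resume_i <- 1L + gd
  i <- resume_i

  while (TRUE) {
    # next upward crossing of thr at or after i (vectorized scan in chunks)
    found <- NA_integer_
    while (i <= n) {
      j_hi <- min(n, i + as.integer(60 * rate_hz))
      seg <- filt[i:j_hi]
      hits <- which(seg[-1] >= thr & seg[-length(seg)] < thr)
      # threshold updates occur on the wall-clock grid; stop the scan there
      lim_i <- time_to_index(next_update, rate_hz, n) + gd
      if (length(hits) && (i + hits[1]) <= lim_i) { found <- i + hits[1]; break }
      if (j_hi >= lim_i && next_update < dur) break
      if (j_hi >= n) break
      i <- j_hi
    }
    # scheduled parameter update reached before the next crossing?
    if ((is.na(found) || t_of(found) >= next_update) && next_update < dur) {
      win <- det_cross >= next_update - protocol$threshold_update_period_s
      if (any(win)) {
        thr <- stats::median(det_amp[win])
        if (protocol$delay_mode == "adaptive") {
          delay_s <- min(0.6, max(0.08, mean(det_p2t[win])))
        }
      }
      thr_trace[[length(thr_trace) + 1L]] <- c(next_update, thr)
      delay_trace[[length(delay_trace) + 1L]] <- c(next_update, delay_s)
      next_update <- next_update + protocol$threshold_update_period_s
      i <- max(i, time_to_index(next_update - protocol$threshold_update_period_s, rate_hz, n) + gd)
      next
    }
    if (is.na(found)) break
    c_i <- found
    # half-wave peak: maximum until the next downward zero crossing
    j <- c_i
    while (j < n && filt[j + 1L] > 0) j <- j + 1L
    pk_rel <- which.max(filt[c_i:j])
    pk_i <- c_i + pk_rel - 1L
    amp <- filt[pk_i]
    # trough: minimum until the next upward zero crossing after j
    j2 <- j
    while (j2 < n && filt[j2 + 1L] <= 0) j2 <- j2 + 1L
    tr_i <- if (j2 > j) j + which.min(filt[(j + 1L):j2]) else j
    det_cross <- c(det_cross, t_of(c_i)); det_peak <- c(det_peak, t_of(pk_i))
    det_amp <- c(det_amp, amp); det_p2t <- c(det_p2t, (tr_i - pk_i) / rate_hz)

    blk <- stim_block_of(t_of(c_i))
    if (!is.na(blk)) {
      st <- if (protocol$mode == "sync") {
        t_of(c_i) + delay_s
      } else {
        cycle <- if (length(det_cross) >= 3) {
          stats::median(diff(utils::tail(det_cross, 10)))
        } else 1
        t_of(c_i) + stats::runif(1, 0, max(0.2, cycle))
      }
      if (st < bl[blk, 2] && st < dur) {
        stim_time <- c(stim_time, st); stim_cross <- c(stim_cross, t_of(c_i))
        stim_peak <- c(stim_peak, t_of(pk_i)); stim_block <- c(stim_block, blk)
        resume_i <- time_to_index(st + protocol$lockout_s, rate_hz, n) + gd
        i <- max(resume_i, j)
        next
      }
    }
    i <- max(j, c_i + 1L)  # wait out the current half-wave
  }

  tt <- do.call(rbind, thr_trace); dt <- do.call(rbind, delay_trace)
  structure(list(
    stims = tibble::tibble(time_s = stim_time, block = stim_block,
                           crossing_s = stim_cross, peak_s = stim_peak,
                           delay_from_peak_s = stim_time - stim_peak),
    detections = tibble::tibble(crossing_s = det_cross, peak_s = det_peak,
                                amp_uv = det_amp, peak_to_trough_s = det_p2t),
    blocks = blocks_tbl,
    threshold_trace = tibble::tibble(time_s = tt[, 1], threshold_uv = tt[, 2]),
    delay_trace = tibble::tibble(time_s = dt[, 1], delay_s = dt[, 2]),
    protocol = protocol, rate_hz = rate_hz),
    class = "sleeploop_stimlog")
}

#' @export
print.sleeploop_stimlog <- function(x, ...) {
  cat(sprintf("<sleeploop_stimlog> %d stimulation(s) in %d STIM block(s), mode %s\n",
              nrow(x$stims), sum(x$blocks$kind == "STIM"), x$protocol$mode))
  invisible(x)
}

#' Calibrate the trigger delay from pre-recorded sleep
#'
#' The controller's delay is anchored at the online threshold crossing, but
#' the in-phase criterion is defined relative to the offline slow-wave
#' positive peak, which the crossing precedes by a geometry-dependent gap.
#' This reproduces the participant-specific delay calibration: on a stretch
#' of pre-recorded sleep, online crossings of `initial_threshold_uv` are
#' paired with the next offline slow-wave candidate peak, and the delay is
#' set to the mean crossing-to-peak gap plus `target_after_peak_ms` (the
#' center of the 80-280 ms in-phase window by default).
#'
#' @param x pre-sleep probe signal, microvolts.
#' @param rate_hz sampling rate.
#' @param protocol a [stim_protocol()] (threshold and filter order are
#'   taken from it).
#' @param target_after_peak_ms intended stimulation delay after the
#'   offline positive peak (default 180).
#' @return calibrated delay in ms, bounded to [80, 600].
#' @export
calibrate_delay <- function(x, rate_hz, protocol = stim_protocol(),
                            target_after_peak_ms = 180) {
  cand <- detect_slow_waves(x, rate_hz, amplitude_criterion = FALSE)
  if (nrow(cand) < 5) stop("too few slow-wave candidates to calibrate", call. = FALSE)
  b <- signal::fir1(protocol$fir_order, c(0.5, 4) / (rate_hz / 2), type = "pass")
  filt <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
  filt[is.na(filt)] <- 0
  gd <- protocol$fir_order / 2
  thr <- protocol$initial_threshold_uv
  n <- length(filt)
  up <- which(filt[-n] < thr & filt[-1] >= thr)
  cross_s <- (up - gd) / rate_hz
  gaps <- vapply(cross_s, function(tc) {
    nxt <- cand$peak_s[cand$peak_s >= tc - 0.2]
    if (length(nxt)) nxt[1] - tc else NA_real_
  }, 0)
  gaps <- gaps[is.finite(gaps) & gaps >= -0.2 & gaps < 1]
  if (length(gaps) < 5) stop("too few crossing-peak pairs to calibrate", call. = FALSE)
  min(600, max(80, 1000 * mean(gaps) + target_after_peak_ms))
}

#' Post-hoc audit of stimulation timing against offline slow-wave peaks
#'
#' For each stimulation, the delay to the immediately preceding offline
#' slow-wave positive peak is measured; a session is classified as
#' sync-stimulation when strictly more than `sync_fraction` of delays fall
#' inside `window_ms`, and mixed otherwise.
#'
#' @param stim_times_s stimulation timestamps, or a `sleeploop_stimlog`.
#' @param peak_times_s offline positive-peak times (seconds) on the probe
#'   channel — typically all duration-qualified slow-wave candidates from
#'   [detect_slow_waves()] with `amplitude_criterion = FALSE`.
#' @param window_ms in-phase delay window, ms (default `c(80, 280)`).
#' @param sync_fraction classification threshold (default 0.55, strict).
#' @return list with `per_stim` (tibble: `time_s`, `delay_ms`), `fraction`
#'   (share of delays inside the window), `mean_delay_ms`, and
#'   `classification` (`"sync"`/`"mixed"`).
#' @export
audit_stim_timing <- function(stim_times_s, peak_times_s,
                              window_ms = c(80, 280), sync_fraction = 0.55) {
  if (inherits(stim_times_s, "sleeploop_stimlog")) stim_times_s <- stim_times_s$stims$time_s
  peak_times_s <- sort(peak_times_s)
  if (length(peak_times_s) == 0) stop("no offline peaks supplied", call. = FALSE)
  delays <- vapply(stim_times_s, function(t) {
    prev <- peak_times_s[peak_times_s <= t]
    if (length(prev)) (t - prev[length(prev)]) * 1000 else Inf
  }, 0)
  frac <- mean(delays >= window_ms[1] & delays <= window_ms[2])
  list(per_stim = tibble::tibble(time_s = stim_times_s, delay_ms = delays),
       fraction = frac,
       mean_delay_ms = mean(delays[is.finite(delays)]),
       classification = if (isTRUE(frac > sync_fraction)) "sync" else "mixed")
}

#' Charge density per phase of a stimulation pulse train
#'
#' `current x single-phase width / contact area`, reported in microcoulombs
#' per square centimeter per phase.
#'
#' @param current_ma pulse current, mA.
#' @param pulse_width_us single-phase pulse width, microseconds.
#' @param contact_area_cm2 contact surface area, cm^2.
#' @return charge density, uC/cm^2 per phase.
#' @examples
#' charge_density(1.5, 100, 0.06)  # 2.5
#' @export
charge_density <- function(current_ma, pulse_width_us, contact_area_cm2) {
  if (contact_area_cm2 <= 0) stop("contact area must be positive", call. = FALSE)
  stopifnot(current_ma >= 0, pulse_width_us > 0)
  (current_ma * 1e-3) * (pulse_width_us * 1e-6) / contact_area_cm2 * 1e6
}
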