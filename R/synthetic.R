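#' Configuration for the synthetic iEEG generator
#'
#' Builds a validated parameter list for [generate_recording()]. Defaults
#' describe one NREM-dominated recording segment of the kind the detectors
#' and the closed-loop simulator are designed for: 1/f background with mains
#' hum, slow waves as single raised-cosine cycles (positive/inactive half
#' followed by negative/active half), sigma-band spindle bursts preferentially
#' following slow-wave positive peaks, brief 80-100 Hz ripples coupled to the
#' slow-wave cycle, and optional interictal-discharge-like transients.
#'
#' @param duration_s total recording length, seconds.
#' @param rate_hz sampling rate, samples/s. Must exceed twice the highest
#'   injected frequency (ripple band or 60-Hz line noise).
#' @param n_channels number of channels; events are injected independently
#'   per channel.
#' @param state_schedule tibble or data.frame with columns `state`
#'   (`"NREM"`/`"DESYNC"`) and `duration_s`; `NULL` means all-NREM.
#' @param sw_rate_per_min slow-wave rate within NREM, events/min.
#' @param sw_amp_uv mean slow-wave peak-to-trough amplitude, microvolts
#'   (individual amplitudes are drawn with 15% coefficient of variation).
#' @param sw_freq_hz two-element range of slow-wave frequencies; one cycle of
#'   frequency f lasts 1/f s, so the default keeps durations in 0.8-1.8 s.
#' @param spindle_rate_per_min,spindle_freq_hz,spindle_amp_uv spindle rate
#'   (events/min in NREM), carrier frequency (Hz, within 9-16), and envelope
#'   peak amplitude (microvolts).
#' @param spindle_coupling_prob probability that a spindle peak is placed at
#'   most 1.5 s after some slow-wave positive peak.
#' @param ripple_rate_per_min,ripple_freq_hz,ripple_amp_uv ripple rate,
#'   carrier frequency (Hz, within 80-100) and amplitude.
#' @param ripple_coupling_prob probability a ripple is timed relative to a
#'   slow-wave positive peak rather than uniformly.
#' @param ripple_coupling_delay_ms ripple peak delay from the slow-wave
#'   positive peak when coupled, ms.
#' @param ied_rate_per_min rate of interictal-discharge-like biphasic
#'   transients (duration < 70 ms), events/min.
#' @param ied_amp_sd IED amplitude in multiples of the composite NREM signal SD.
#' @param line_noise_amp_uv 60-Hz line-noise amplitude, microvolts.
#' @param noise_exponent background spectral slope a in 1/f^a power.
#' @param background_sd_uv broadband background SD, microvolts.
#' @param nrem_delta_uv,nrem_sigma_uv SD of continuous band-limited activity
#'   (0.5-2 Hz and 9-16 Hz) added during NREM only; gives NREM epochs the
#'   elevated slow-wave and sigma power that sleep scoring keys on, and the
#'   delta component supplies the population of small slow-wave candidates
#'   against which the detector's 75th-percentile amplitude criterion is
#'   meaningful.
#' @param sw_phase_lag_deg per-channel slow-wave phase lag, degrees (recycled
#'   over channels); shifts that channel's injected slow-wave times by
#'   `lag/360 / f`. Cross-regional lags are not quantitatively constrained by
#'   the literature, so this is an explicit knob rather than a distribution.
#' @param seed integer seed; fully determines the output.
#' @return a named list of class `sleeploop_config`.
#' @export
synthetic_config <- function(duration_s = 600,
                             rate_hz = 2000,
                             n_channels = 1,
                             state_schedule = NULL,
                             sw_rate_per_min = 11,
                             sw_amp_uv = 350,
                             sw_freq_hz = c(0.75, 1.15),
                             spindle_rate_per_min = 4,
                             spindle_freq_hz = 13,
                             spindle_amp_uv = 30,
                             spindle_coupling_prob = 0.7,
                             ripple_rate_per_min = 0,
                             ripple_freq_hz = 90,
                             ripple_amp_uv = 20,
                             ripple_coupling_prob = 0.7,
                             ripple_coupling_delay_ms = 200,
                             ied_rate_per_min = 0,
                             ied_amp_sd = 8,
                             line_noise_amp_uv = 5,
                             noise_exponent = 1.5,
                             background_sd_uv = 10,
                             nrem_delta_uv = 15,
                             nrem_sigma_uv = 2,
                             sw_phase_lag_deg = 0,
                             seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(sw_rate_per_min, spindle_rate_per_min, ripple_rate_per_min, ied_rate_per_min)
  if (any(rates < 0)) stop("event rates must be non-negative", call. = FALSE)
  stopifnot(duration_s > 0, rate_hz > 0, n_channels >= 1)
  if (spindle_freq_hz < 9 || spindle_freq_hz > 16) stop("spindle_freq_hz must lie in [9, 16]", call. = FALSE)
  if (ripple_freq_hz < 80 || ripple_freq_hz > 100) stop("ripple_freq_hz must lie in [80, 100]", call. = FALSE)
  if (spindle_coupling_prob < 0 || spindle_coupling_prob > 1) stop("spindle_coupling_prob must lie in [0, 1]", call. = FALSE)
  fmax <- max(if (ripple_rate_per_min > 0) ripple_freq_hz else 0,
              if (spindle_rate_per_min > 0) spindle_freq_hz else 0,
              if (line_noise_amp_uv > 0) 60 else 0,
              max(sw_freq_hz))
  if (rate_hz <= 2 * fmax) {
    stop(sprintf("sampling rate %g Hz is below Nyquist for the requested %g Hz content",
                 rate_hz, fmax), call. = FALSE)
  }
  if (is.null(state_schedule)) {
    state_schedule <- tibble::tibble(state = "NREM", duration_s = duration_s)
  }
  state_schedule <- tibble::as_tibble(state_schedule)
  stopifnot(all(state_schedule$state %in% c("NREM", "DESYNC")))
  if (abs(sum(state_schedule$duration_s) - duration_s) > 1e-9) {
    stop("state_schedule durations must sum to duration_s", call. = FALSE)
  }
  cfg$state_schedule <- state_schedule
  class(cfg) <- "sleeploop_config"
  cfg
}

# state runs as tibble(state, start_s, end_s)
state_runs <- function(config) {
  sched <- config$state_schedule
  ends <- cumsum(sched$duration_s)
  tibble::tibble(state = sched$state, start_s = c(0, ends[-length(ends)]), end_s = ends)
}

# Draw non-overlapping event placements of one kind inside the NREM runs.
# Returns tibble(onset_s, offset_s). With process = "poisson", counts are
# Poisson and positions uniform; overlapping draws are re-drawn up to a
# retry cap and then dropped with a warning. With process = "renewal",
# events form a quasi-rhythmic train: inter-onset gaps are min_gap_s plus a
# gamma(shape)-distributed wait whose mean matches the requested rate —
# the sub-Poisson regularity of slow-oscillation trains.
draw_event_times <- function(nrem, rate_per_min, dur_fn, max_try = 60L,
                             process = c("poisson", "renewal"),
                             min_gap_s = 0, gamma_shape = 3) {
  process <- match.arg(process)
  placed_on <- numeric(0); placed_off <- numeric(0)
  for (i in seq_len(nrow(nrem))) {
    span <- nrem$end_s[i] - nrem$start_s[i]
    if (rate_per_min <= 0) next
    if (process == "renewal") {
      mean_gap <- 60 / rate_per_min
      mean_dur <- mean(replicate(20, dur_fn()))
      wait_mean <- max(0.05, mean_gap - min_gap_s - mean_dur)
      t0 <- nrem$start_s[i] +
        stats::rgamma(1, gamma_shape, gamma_shape / wait_mean)
      repeat {
        d <- dur_fn()
        if (t0 + d > nrem$end_s[i]) break
        placed_on <- c(placed_on, t0); placed_off <- c(placed_off, t0 + d)
        t0 <- t0 + d + min_gap_s + stats::rgamma(1, gamma_shape, gamma_shape / wait_mean)
      }
    } else {
      n <- stats::rpois(1L, rate_per_min * span / 60)
      dropped <- 0L
      for (k in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(max_try)) {
          d <- dur_fn()
          if (d >= span) break
          on <- stats::runif(1L, nrem$start_s[i], nrem$end_s[i] - d)
          off <- on + d
          if (!any(on - min_gap_s < placed_off & off + min_gap_s > placed_on)) {
            placed_on <- c(placed_on, on); placed_off <- c(placed_off, off)
            ok <- TRUE
            break
          }
        }
        if (!ok) dropped <- dropped + 1L
      }
      if (dropped > 0L) {
        warning(sprintf("dropped %d event(s) that could not be placed without overlap", dropped))
      }
    }
  }
  ord <- order(placed_on)
  tibble::tibble(onset_s = placed_on[ord], offset_s = placed_off[ord])
}

# Tukey (tapered-cosine) envelope: flat center, cosine ramps over a
# fraction `taper` of the length at each end.
tukey_env <- function(len, taper = 0.3) {
  u <- (seq_len(len) - 1) / (len - 1)
  env <- rep(1, len)
  lo <- u < taper
  hi <- u > 1 - taper
  env[lo] <- 0.5 * (1 - cos(pi * u[lo] / taper))
  env[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / taper))
  env
}

# Band-limited Gaussian activity restricted to NREM runs, zero elsewhere.
nrem_band_noise <- function(n, rate_hz, nrem_idx, low_hz, high_hz, sd_uv) {
  if (sd_uv <= 0 || length(nrem_idx) == 0L) return(numeric(n))
  x <- butter_bandpass(stats::rnorm(n), rate_hz, low_hz, high_hz, order = 2L)
  x <- x / stats::sd(x[nrem_idx]) * sd_uv
  out <- numeric(n)
  out[nrem_idx] <- x[nrem_idx]
  # taper 0.5 s at run edges to avoid step discontinuities
  out
}

#' Generate a ground-truth-annotated synthetic iEEG recording
#'
#' Synthesizes the signal described by a [synthetic_config()]: per channel,
#' 1/f background plus 60-Hz line noise; during NREM, continuous delta and
#' sigma band activity plus injected slow waves (one raised-cosine cycle,
#' positive/inactive half then negative/active half), spindle bursts
#' (Hann-windowed sigma oscillation, 0.5-2 s), ripples (Hann-windowed 80-100
#' Hz burst) and biphasic interictal-discharge-like transients. Every
#' injected event is recorded in the returned ground-truth ledger.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{recording}{a [new_recording()] object.}
#'     \item{truth}{list with `events` (tibble: `channel`, `kind`, `onset_s`,
#'       `offset_s`, `peak_s`, `trough_s`, `freq_hz`, `amp_uv`), `epochs`
#'       (tibble: `epoch_start_s`, `state` on the 30-s grid), and `config`.}
#'   }
#' @examples
#' out <- generate_recording(synthetic_config(duration_s = 60, rate_hz = 200,
#'                                            seed = 7))
#' out$recording
#' dplyr::count(out$truth$events, kind)
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sleeploop_config"))
  set.seed(config$seed)
  rate <- config$rate_hz
  n <- round(config$duration_s * rate)
  t <- (seq_len(n) - 1L) / rate
  runs <- state_runs(config)
  nrem <- runs[runs$state == "NREM", , drop = FALSE]
  nrem_mask <- rep(FALSE, n)
  for (i in seq_len(nrow(nrem))) {
    nrem_mask[t >= nrem$start_s[i] & t < nrem$end_s[i]] <- TRUE
  }
  nrem_idx <- which(nrem_mask)

  lags <- rep_len(config$sw_phase_lag_deg, config$n_channels)
  samples <- matrix(0, nrow = config$n_channels, ncol = n)
  all_events <- vector("list", config$n_channels)

  for (ch in seq_len(config$n_channels)) {
    x <- colored_noise(n, config$noise_exponent) * config$background_sd_uv
    if (config$line_noise_amp_uv > 0) {
      x <- x + config$line_noise_amp_uv * sin(2 * pi * 60 * t + stats::runif(1, 0, 2 * pi))
    }
    x <- x + nrem_band_noise(n, rate, nrem_idx, 0.5, 2, config$nrem_delta_uv)
    x <- x + nrem_band_noise(n, rate, nrem_idx, 9, 16, config$nrem_sigma_uv)

    ev <- list()

    # --- slow waves: one raised-cosine cycle, OFF (positive) then ON (negative),
    # placed as a quasi-rhythmic renewal train with a refractory gap
    sw <- draw_event_times(nrem, config$sw_rate_per_min,
                           dur_fn = function() 1 / stats::runif(1, config$sw_freq_hz[1], config$sw_freq_hz[2]),
                           process = "renewal", min_gap_s = 0.6)
    if (nrow(sw) > 0) {
      lag_s <- lags[ch] / 360 * (sw$offset_s - sw$onset_s)
      sw$onset_s <- sw$onset_s + lag_s
      sw$offset_s <- sw$offset_s + lag_s
      keep <- sw$offset_s <= config$duration_s
      sw <- sw[keep, , drop = FALSE]
    }
    if (nrow(sw) > 0) {
      amp <- pmax(config$sw_amp_uv * (1 + 0.15 * stats::rnorm(nrow(sw))), 0.3 * config$sw_amp_uv)
      for (k in seq_len(nrow(sw))) {
        i0 <- time_to_index(sw$onset_s[k], rate, n)
        i1 <- time_to_index(sw$offset_s[k], rate, n)
        idx <- i0:i1
        ph <- (idx - i0) / (i1 - i0)
        # short edge taper keeps the waveform C1-smooth (no spectral kinks)
        x[idx] <- x[idx] + amp[k] / 2 * sin(2 * pi * ph) * tukey_env(length(idx), 0.1)
      }
      dur <- sw$offset_s - sw$onset_s
      ev$slow_wave <- tibble::tibble(
        kind = "slow_wave", onset_s = sw$onset_s, offset_s = sw$offset_s,
        peak_s = sw$onset_s + dur / 4, trough_s = sw$onset_s + 3 * dur / 4,
        freq_hz = 1 / dur, amp_uv = amp)
    }

    # --- spindles, preferentially after slow-wave positive peaks
    sp <- draw_event_times(nrem, config$spindle_rate_per_min,
                           dur_fn = function() stats::runif(1, 0.6, 1.8),
                           min_gap_s = 1)
    if (nrow(sp) > 0 && !is.null(ev$slow_wave) && config$spindle_coupling_prob > 0 &&
        nrow(ev$slow_wave) > 0) {
      swp <- ev$slow_wave$peak_s
      for (k in seq_len(nrow(sp))) {
        if (stats::runif(1) < config$spindle_coupling_prob) {
          d <- sp$offset_s[k] - sp$onset_s[k]
          anchor <- sample(swp, 1L)
          delay <- stats::runif(1, 0.05, max(0.06, 1.5 - d / 2))
          peak <- anchor + delay
          on <- peak - d / 2
          if (on >= 0 && on + d <= config$duration_s) {
            sp$onset_s[k] <- on; sp$offset_s[k] <- on + d
          }
        }
      }
      ord <- order(sp$onset_s)
      sp <- sp[ord, , drop = FALSE]
      # re-drawn coupled placements may collide; drop later duplicates
      keep <- rep(TRUE, nrow(sp))
      if (nrow(sp) > 1) {
        for (k in 2:nrow(sp)) if (sp$onset_s[k] < max(sp$offset_s[seq_len(k - 1L)][keep[seq_len(k - 1L)]])) keep[k] <- FALSE
      }
      sp <- sp[keep, , drop = FALSE]
    }
    if (nrow(sp) > 0) {
      for (k in seq_len(nrow(sp))) {
        i0 <- time_to_index(sp$onset_s[k], rate, n)
        i1 <- time_to_index(sp$offset_s[k], rate, n)
        idx <- i0:i1
        env <- tukey_env(length(idx), taper = 0.3)  # waxing-waning burst
        x[idx] <- x[idx] + config$spindle_amp_uv * env *
          sin(2 * pi * config$spindle_freq_hz * (idx - i0) / rate)
      }
      ev$spindle <- tibble::tibble(
        kind = "spindle", onset_s = sp$onset_s, offset_s = sp$offset_s,
        peak_s = (sp$onset_s + sp$offset_s) / 2, trough_s = NA_real_,
        freq_hz = config$spindle_freq_hz, amp_uv = config$spindle_amp_uv)
    }

    # --- ripples, coupled to the slow-wave positive peak at a fixed delay
    rp <- draw_event_times(nrem, config$ripple_rate_per_min,
                           dur_fn = function() stats::runif(1, 0.05, 0.1))
    if (nrow(rp) > 0 && !is.null(ev$slow_wave) && nrow(ev$slow_wave) > 0 &&
        config$ripple_coupling_prob > 0) {
      swp <- ev$slow_wave$peak_s
      for (k in seq_len(nrow(rp))) {
        if (stats::runif(1) < config$ripple_coupling_prob) {
          d <- rp$offset_s[k] - rp$onset_s[k]
          peak <- sample(swp, 1L) + config$ripple_coupling_delay_ms / 1000
          on <- peak - d / 2
          if (on >= 0 && on + d <= config$duration_s) {
            rp$onset_s[k] <- on; rp$offset_s[k] <- on + d
          }
        }
      }
      ord <- order(rp$onset_s)
      rp <- rp[ord, , drop = FALSE]
      keep <- rep(TRUE, nrow(rp))
      if (nrow(rp) > 1) {
        for (k in 2:nrow(rp)) if (rp$onset_s[k] < max(rp$offset_s[seq_len(k - 1L)][keep[seq_len(k - 1L)]])) keep[k] <- FALSE
      }
      rp <- rp[keep, , drop = FALSE]
    }
    if (nrow(rp) > 0) {
      for (k in seq_len(nrow(rp))) {
        i0 <- time_to_index(rp$onset_s[k], rate, n)
        i1 <- time_to_index(rp$offset_s[k], rate, n)
        idx <- i0:i1
        env <- 0.5 - 0.5 * cos(2 * pi * (idx - i0) / (i1 - i0))
        x[idx] <- x[idx] + config$ripple_amp_uv * env *
          sin(2 * pi * config$ripple_freq_hz * (idx - i0) / rate)
      }
      ev$ripple <- tibble::tibble(
        kind = "ripple", onset_s = rp$onset_s, offset_s = rp$offset_s,
        peak_s = (rp$onset_s + rp$offset_s) / 2, trough_s = NA_real_,
        freq_hz = config$ripple_freq_hz, amp_uv = config$ripple_amp_uv)
    }

    # --- IED-like biphasic transients (one sharp cycle, < 70 ms)
    ied <- draw_event_times(nrem, config$ied_rate_per_min,
                            dur_fn = function() stats::runif(1, 0.03, 0.06))
    if (nrow(ied) > 0) {
      # amplitude in SD units of the composite NREM signal, the scale the
      # IED detector z-scores against
      amp <- config$ied_amp_sd * stats::sd(x[nrem_idx])
      for (k in seq_len(nrow(ied))) {
        i0 <- time_to_index(ied$onset_s[k], rate, n)
        i1 <- time_to_index(ied$offset_s[k], rate, n)
        idx <- i0:i1
        x[idx] <- x[idx] + amp * sin(2 * pi * (idx - i0) / (i1 - i0))
      }
      ev$ied <- tibble::tibble(
        kind = "ied", onset_s = ied$onset_s, offset_s = ied$offset_s,
        peak_s = ied$onset_s + (ied$offset_s - ied$onset_s) / 4, trough_s = NA_real_,
        freq_hz = NA_real_, amp_uv = amp)
    }

    samples[ch, ] <- x
    events <- dplyr::bind_rows(ev)
    if (nrow(events) > 0) events$channel <- paste0("ch", ch)
    all_events[[ch]] <- events
  }

  events <- dplyr::bind_rows(all_events)
  if (nrow(events) == 0) {
    events <- tibble::tibble(channel = character(), kind = character(),
                             onset_s = numeric(), offset_s = numeric(),
                             peak_s = numeric(), trough_s = numeric(),
                             freq_hz = numeric(), amp_uv = numeric())
  } else {
    events <- dplyr::arrange(
      dplyr::select(events, "channel", "kind", "onset_s", "offset_s",
                    "peak_s", "trough_s", "freq_hz", "amp_uv"),
      .data$channel, .data$kind, .data$onset_s)
  }

  n_epochs <- floor(config$duration_s / 30)
  epoch_start <- (seq_len(max(n_epochs, 1L)) - 1L) * 30
  ep_state <- vapply(epoch_start, function(s) {
    mid <- s + 15
    st <- runs$state[runs$start_s <= mid & runs$end_s > mid]
    if (length(st)) st[1] else runs$state[nrow(runs)]
  }, "")

  chans <- tibble::tibble(
    label = paste0("ch", seq_len(config$n_channels)),
    region = rep_len(c("MTL", "PFC"), config$n_channels),
    hemisphere = "L", tissue = "gray", kind = "macro",
    electrode = paste0("e", seq_len(config$n_channels)))
  rec <- new_recording(samples, rate_hz = rate, channels = chans)

  list(recording = rec,
       truth = list(events = events,
                    epochs = tibble::tibble(epoch_start_s = epoch_start, state = ep_state),
                    config = config))
}

#' Generate phase-modulated Poisson spike trains
#'
#' Simulates inhomogeneous Poisson units with rate
#' `lambda(t) = base_rate * (1 + m * cos(phase(t) - phi0))` by thinning
#' against `lambda_max = base_rate * (1 + m)` (exact for an inhomogeneous
#' Poisson process). The expected locking depth of the resulting spike-phase
#' histogram is `2 m / (2 m + 1)`.
#'
#' @param phase_deg per-sample phase in degrees (e.g. from
#'   [slow_wave_phase()]).
#' @param rate_hz sampling rate of `phase_deg`.
#' @param units tibble with columns `unit_id`, `base_rate_hz` (> 0), `m`
#'   (modulation depth in `[0, 1]`) and `phi0_deg` (preferred phase).
#' @param seed integer seed.
#' @return tibble with columns `unit_id`, `time_s` (sorted within unit).
#' @examples
#' ph <- ((seq_len(2000) - 1) / 200 * 360) %% 360 - 180  # 1-Hz phase ramp
#' tr <- generate_spike_trains(ph, 200,
#'   tibble::tibble(unit_id = "u1", base_rate_hz = 5, m = 0.5, phi0_deg = 0),
#'   seed = 1)
#' nrow(tr)
#' @export
generate_spike_trains <- function(phase_deg, rate_hz, units, seed = 1L) {
  units <- tibble::as_tibble(units)
  stopifnot(all(c("unit_id", "base_rate_hz", "m", "phi0_deg") %in% names(units)))
  if (any(units$base_rate_hz <= 0)) stop("base_rate_hz must be positive", call. = FALSE)
  if (any(units$m < 0 | units$m > 1)) {
    stop("modulation depth m must lie in [0, 1] (negative rates otherwise)", call. = FALSE)
  }
  set.seed(seed)
  dur <- length(phase_deg) / rate_hz
  out <- purrr::pmap(units, function(unit_id, base_rate_hz, m, phi0_deg, ...) {
    lam_max <- base_rate_hz * (1 + m)
    n_cand <- stats::rpois(1L, lam_max * dur)
    cand <- sort(stats::runif(n_cand, 0, dur))
    ph <- phase_deg[time_to_index(cand, rate_hz, length(phase_deg))]
    lam <- base_rate_hz * (1 + m * cos((ph - phi0_deg) * pi / 180))
    keep <- stats::runif(n_cand) < lam / lam_max
    tibble::tibble(unit_id = unit_id, time_s = cand[keep])
  })
  dplyr::bind_rows(out)
}

#' Generate a synthetic recognition-memory test session
#'
#' Bernoulli "old" responses for a recognition test with `n_targets` learned
#' items and `n_lures` novel items; the expected recognition accuracy
#' (hit rate minus false-alarm rate) equals `p_hit - p_fa`. Reaction times
#' are log-normal; pairing (associate) correctness for recognized targets is
#' Bernoulli with probability `p_pair`.
#'
#' @param p_hit,p_fa probabilities of an "old" response to targets and lures.
#' @param n_targets,n_lures trial counts (defaults 25 and 15).
#' @param rt_meanlog,rt_sdlog log-normal reaction-time parameters (seconds).
#' @param p_pair probability of a correct pairing given a recognized target.
#' @param seed integer seed.
#' @return tibble with columns `item_id`, `is_lure`, `response`
#'   (`"old"`/`"new"`), `pairing_correct` (logical, `NA` where not
#'   applicable) and `rt_s`.
#' @export
generate_behavioral_responses <- function(p_hit, p_fa, n_targets = 25, n_lures = 15,
                                          rt_meanlog = log(0.6), rt_sdlog = 0.3,
                                          p_pair = 0.9, seed = 1L) {
  for (p in c(p_hit, p_fa, p_pair)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  is_lure <- c(rep(FALSE, n_targets), rep(TRUE, n_lures))
  p_old <- ifelse(is_lure, p_fa, p_hit)
  old <- stats::runif(n_targets + n_lures) < p_old
  pairing <- ifelse(!is_lure & old, stats::runif(n_targets + n_lures) < p_pair, NA)
  tibble::tibble(
    item_id = seq_along(is_lure),
    is_lure = is_lure,
    response = ifelse(old, "old", "new"),
    pairing_correct = as.logical(pairing),
    rt_s = stats::rlnorm(length(is_lure), rt_meanlog, rt_sdlog))
}
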