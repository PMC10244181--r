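# Shared fixtures, generated once per test run. All seeds are fixed; every
# fixture is built in code (no stored data).

# sensitivity/precision of detections against ground-truth intervals:
# a detection matches iff its peak lies inside a true interval.
detector_performance <- function(detections, truth) {
  if (nrow(truth) == 0) return(c(sensitivity = NA_real_, precision = NA_real_))
  matched_det <- vapply(seq_len(nrow(detections)), function(i) {
    any(detections$peak_s[i] >= truth$onset_s & detections$peak_s[i] <= truth$offset_s)
  }, logical(1))
  matched_true <- vapply(seq_len(nrow(truth)), function(i) {
    any(detections$peak_s >= truth$onset_s[i] & detections$peak_s <= truth$offset_s[i])
  }, logical(1))
  c(sensitivity = mean(matched_true),
    precision = if (nrow(detections)) mean(matched_det) else 0)
}

# 10-min, 400-Hz high-SNR fixture with all oscillation kinds (built lazily,
# cached for the whole run)
fx_env <- new.env()

fixture_full <- function(seed = 11) {
  key <- paste0("full", seed)
  if (is.null(fx_env[[key]])) {
    cfg <- synthetic_config(duration_s = 600, rate_hz = 400, seed = seed,
                            ripple_rate_per_min = 4)
    fx_env[[key]] <- generate_recording(cfg)
  }
  fx_env[[key]]
}

# short session for closed-loop tests: 720 s at 400 Hz, all NREM
fixture_session <- function(seed = 41) {
  key <- paste0("sess", seed)
  if (is.null(fx_env[[key]])) {
    cfg <- synthetic_config(duration_s = 720, rate_hz = 400, seed = seed)
    fx_env[[key]] <- generate_recording(cfg)
  }
  fx_env[[key]]
}

# stimulation log with a given block layout, built directly
make_stimlog <- function(stim_times, peak_times, blocks) {
  structure(list(
    stims = tibble::tibble(time_s = stim_times, block = 1L,
                           crossing_s = peak_times, peak_s = peak_times,
                           delay_from_peak_s = stim_times - peak_times),
    detections = tibble::tibble(crossing_s = numeric(), peak_s = numeric(),
                                amp_uv = numeric(), peak_to_trough_s = numeric()),
    blocks = blocks,
    threshold_trace = tibble::tibble(time_s = 0, threshold_uv = 80),
    delay_trace = tibble::tibble(time_s = 0, delay_s = 0.4),
    protocol = stim_protocol(), rate_hz = 400), class = "sleeploop_stimlog")
}
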