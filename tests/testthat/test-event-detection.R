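test_that("slow-wave candidates on a sinusoid follow zero-crossing geometry", {
  rate <- 200
  t <- (0:(rate * 60 - 1)) / rate
  ev <- detect_slow_waves(100 * sin(2 * pi * 1 * t), rate)
  cand <- detect_slow_waves(100 * sin(2 * pi * 1 * t), rate, amplitude_criterion = FALSE)
  # every full cycle away from the filter edges is one 1.0-s candidate
  expect_gt(nrow(cand), 50)
  expect_true(all(abs((cand$offset_s - cand$onset_s) - 1) < 0.02))
  # amplitudes tie -> all candidates survive the percentile criterion
  expect_equal(nrow(ev), nrow(cand))
  # positive peak precedes the trough within each event
  expect_true(all(ev$peak_s < ev$trough_s))
})

test_that("slow-wave duration bounds and degenerate inputs behave", {
  rate <- 200
  t <- (0:(rate * 60 - 1)) / rate
  # 2.5-Hz cycles last 0.4 s: all candidates rejected by the duration gate
  expect_equal(nrow(detect_slow_waves(100 * sin(2 * pi * 2.5 * t), rate)), 0)
  expect_equal(nrow(detect_slow_waves(rep(0, rate * 60), rate)), 0)
  expect_error(detect_slow_waves(rnorm(100), rate), "filter order")
})

test_that("detectors recover injected oscillations with >= 0.9 sensitivity/precision", {
  out <- fixture_full(11)
  x <- channel_signal(out$recording, 1)
  tr <- out$truth$events
  sw_perf <- detector_performance(detect_slow_waves(x, 400),
                                  tr[tr$kind == "slow_wave", ])
  sp_perf <- detector_performance(detect_spindles(x, 400),
                                  tr[tr$kind == "spindle", ])
  rp <- detect_ripples(x, 400)
  rp_perf <- detector_performance(rp$events, tr[tr$kind == "ripple", ])
  for (p in list(sw_perf, sp_perf, rp_perf)) {
    expect_gte(p[["sensitivity"]], 0.9)
    expect_gte(p[["precision"]], 0.9)
  }
})

test_that("detections never overlap masked samples", {
  out <- fixture_full(11)
  x <- channel_signal(out$recording, 1)
  n <- length(x)
  mask <- rep(TRUE, n)
  mask[1:(200 * 400)] <- FALSE  # first 200 s invalid
  sw <- detect_slow_waves(x, 400, mask)
  sp <- detect_spindles(x, 400, mask)
  expect_true(all(sw$onset_s >= 200))
  expect_true(all(sp$onset_s >= 200))
})

test_that("within-kind detections are non-overlapping", {
  out <- fixture_full(11)
  x <- channel_signal(out$recording, 1)
  for (ev in list(detect_slow_waves(x, 400), detect_spindles(x, 400),
                  detect_ripples(x, 400)$events)) {
    if (nrow(ev) > 1) {
      expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)] - 1e-9))
    }
  }
})

test_that("spindle channel qualification separates sigma-rich from 1/f channels", {
  cfg <- synthetic_config(duration_s = 400, rate_hz = 200, seed = 51,
                          spindle_rate_per_min = 6)
  x <- channel_signal(generate_recording(cfg)$recording, 1)
  q <- qualify_spindle_channel(x, 200)
  expect_true(q$evaluable)
  expect_true(q$qualified)
  cfg0 <- synthetic_config(duration_s = 400, rate_hz = 200, seed = 52,
                           sw_rate_per_min = 0, spindle_rate_per_min = 0,
                           nrem_delta_uv = 0, nrem_sigma_uv = 0,
                           line_noise_amp_uv = 0)
  x0 <- channel_signal(generate_recording(cfg0)$recording, 1)
  q0 <- qualify_spindle_channel(x0, 200)
  expect_false(q0$qualified)
  # bursts present but outside the analyzed (NREM) mask -> not qualified
  mask <- rep(FALSE, length(x))
  mask[1:(200 * 200)] <- TRUE
  cfg1 <- cfg; cfg1$seed <- 53
  half_burst <- generate_recording(cfg1)
  xh <- channel_signal(half_burst$recording, 1)
  # scramble: evaluate the burst-free half only
  q1 <- qualify_spindle_channel(c(x0[1:(200 * 200)], xh[1:(200 * 200)]), 200,
                                valid_mask = c(rep(TRUE, 200 * 200), rep(FALSE, 200 * 200)))
  expect_false(q1$qualified)
  # too few epochs -> unevaluable
  q2 <- qualify_spindle_channel(x[1:(150 * 200)], 200)
  expect_false(q2$evaluable)
})

test_that("spindle detection flags fast spindles and rejects short bursts", {
  rate <- 400
  set.seed(6)
  x <- sleeploop:::colored_noise(rate * 300, 1.5) * 8
  add_burst <- function(x, at_s, dur_s, freq, amp = 30) {
    i <- round(at_s * rate):(round(at_s * rate) + round(dur_s * rate))
    x[i] <- x[i] + amp * sin(2 * pi * freq * (i - i[1]) / rate) *
      sleeploop:::tukey_env(length(i))
    x
  }
  x1 <- add_burst(x, 100, 1.0, 12)
  det <- detect_spindles(x1, rate)
  hit <- det[det$peak_s > 99.9 & det$peak_s < 101.1, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$is_fast)
  expect_lt(abs(hit$peak_freq_hz - 12), 1)
  # 0.3-s burst is below the duration gate
  x2 <- add_burst(x, 100, 0.3, 12)
  det2 <- detect_spindles(x2, rate)
  expect_equal(nrow(det2[det2$peak_s > 99.9 & det2$peak_s < 100.4, ]), 0)
  expect_error(detect_spindles(rep(0, rate * 10), rate), "zero-variance")
})

test_that("broadband bursts with 20-30 Hz content are vetoed", {
  rate <- 400
  set.seed(7)
  x <- sleeploop:::colored_noise(rate * 300, 1.5) * 8
  i <- (100 * rate):(101 * rate)
  env <- sleeploop:::tukey_env(length(i))
  # sigma burst with strong 25-Hz content riding on it
  x[i] <- x[i] + env * (30 * sin(2 * pi * 12 * (i - i[1]) / rate) +
                          40 * sin(2 * pi * 25 * (i - i[1]) / rate))
  det <- detect_spindles(x, rate)
  expect_equal(nrow(det[det$peak_s > 99.9 & det$peak_s < 101.1, ]), 0)
})

test_that("bipolar referencing subtracts the white-matter contact", {
  set.seed(8)
  g <- rnorm(1000); r <- rnorm(1000)
  expect_equal(bipolar_reference(g, g), rep(0, 1000))
  expect_equal(bipolar_reference(g + r, g), r)
  t <- (0:999) / 400
  art <- 25 * sin(2 * pi * 60 * t)
  expect_equal(bipolar_reference(g + art, r + art), g - r)
  expect_error(bipolar_reference(g, r[1:10]), "length")
  expect_error(bipolar_reference(g, r, 400, 500), "rates differ")
})

test_that("ripple detection honors duration, oscillation and baseline criteria", {
  rate <- 400
  set.seed(9)
  x <- sleeploop:::colored_noise(rate * 300, 1.5) * 8
  # physiological SNR (~8x the ripple-band background RMS); at extreme
  # amplitudes the band-pass smear alone can exceed the duration criterion
  add_ripple <- function(x, at_s, dur_s) {
    i <- round(at_s * rate):(round(at_s * rate) + round(dur_s * rate))
    x[i] <- x[i] + 8 * sin(2 * pi * 90 * (i - i[1]) / rate) *
      (0.5 - 0.5 * cos(2 * pi * seq_along(i) / length(i)))
    x
  }
  x1 <- add_ripple(x, 150, 0.06)
  r1 <- detect_ripples(x1, rate)
  expect_equal(nrow(r1$events[r1$events$peak_s > 149.9 & r1$events$peak_s < 150.2, ]), 1)
  # a 30-ms burst is under the 38-ms minimum
  x2 <- add_ripple(x, 150, 0.03)
  r2 <- detect_ripples(x2, rate)
  expect_equal(nrow(r2$events[r2$events$peak_s > 149.9 & r2$events$peak_s < 150.1, ]), 0)
  # channel qualification needs 20 baseline detections
  x3 <- x
  for (k in 1:12) x3 <- add_ripple(x3, 10 + 5 * k, 0.06)
  r3 <- detect_ripples(x3, rate, baseline_window = c(0, 120))
  expect_false(r3$qualified)
  expect_equal(r3$n_baseline, sum(r3$events$peak_s < 120))
  expect_error(detect_ripples(x, 150), "too low")
})

test_that("the ripple duration criterion equals 38 ms for 3 cycles at 80 Hz", {
  expect_equal(ripple_min_duration_ms(), 38)
  expect_equal(ripple_min_duration_ms(3, 100), 30)
})
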