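test_that("event-free configuration yields pure background and an empty ledger", {
  cfg <- synthetic_config(duration_s = 60, rate_hz = 200, seed = 1,
                          sw_rate_per_min = 0, spindle_rate_per_min = 0,
                          ripple_rate_per_min = 0, ied_rate_per_min = 0,
                          line_noise_amp_uv = 0, nrem_delta_uv = 0, nrem_sigma_uv = 0)
  out <- generate_recording(cfg)
  expect_equal(nrow(out$truth$events), 0)
  expect_equal(ncol(out$recording$samples), 60 * 200)
  # 1/f background: low-frequency Welch power dominates high-frequency
  x <- channel_signal(out$recording, 1)
  expect_gt(welch_band_power(x, 200, 0.5, 4), welch_band_power(x, 200, 30, 60))
})

test_that("identical seeds reproduce the recording and ground truth bit for bit", {
  cfg <- synthetic_config(duration_s = 60, rate_hz = 200, seed = 7,
                          ied_rate_per_min = 1)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("spindle ledger counts are consistent and durations respect bounds", {
  cfg <- synthetic_config(duration_s = 600, rate_hz = 200, seed = 3,
                          spindle_rate_per_min = 3)
  out <- generate_recording(cfg)
  sp <- out$truth$events[out$truth$events$kind == "spindle", ]
  durs <- sp$offset_s - sp$onset_s
  expect_true(all(durs >= 0.5 & durs <= 2))
  # realized count is a plausible draw for a 3/min rate over 10 min
  expect_gt(nrow(sp), stats::qpois(0.0005, 30))
  expect_lt(nrow(sp), stats::qpois(0.9995, 30))
  # within-kind intervals are non-overlapping on each channel
  expect_true(all(diff(sp$onset_s) >= 0))
  expect_true(all(sp$onset_s[-1] >= sp$offset_s[-nrow(sp)] - 1e-9))
})

test_that("all injected events lie inside the recording and NREM runs", {
  sched <- tibble::tibble(state = c("NREM", "DESYNC", "NREM"),
                          duration_s = c(120, 60, 120))
  cfg <- synthetic_config(duration_s = 300, rate_hz = 200, seed = 5,
                          ied_rate_per_min = 2)
  cfg$state_schedule <- sched
  out <- generate_recording(cfg)
  ev <- out$truth$events
  expect_true(all(ev$onset_s >= 0 & ev$offset_s <= 300))
  in_desync <- ev$onset_s < 180 & ev$offset_s > 120
  expect_false(any(in_desync))
})

test_that("full coupling places every spindle peak within 1.5 s after a slow-wave peak", {
  cfg <- synthetic_config(duration_s = 600, rate_hz = 200, seed = 9,
                          spindle_coupling_prob = 1)
  out <- generate_recording(cfg)
  ev <- out$truth$events
  swp <- ev$peak_s[ev$kind == "slow_wave"]
  spp <- ev$peak_s[ev$kind == "spindle"]
  delays <- vapply(spp, function(p) {
    prev <- swp[swp < p]
    if (length(prev)) p - max(prev) else Inf
  }, 0)
  expect_true(all(delays <= 1.5 + 1e-9))
})

test_that("NREM epochs carry more slow-wave and sigma power than desynchronized ones", {
  sched <- tibble::tibble(state = c("NREM", "DESYNC"), duration_s = c(150, 150))
  cfg <- synthetic_config(duration_s = 300, rate_hz = 200, seed = 13)
  cfg$state_schedule <- sched
  x <- channel_signal(generate_recording(cfg)$recording, 1)
  nrem <- x[1:(150 * 200)]
  des <- x[(150 * 200 + 1):(300 * 200)]
  expect_gt(welch_band_power(nrem, 200, 0.5, 4), 2 * welch_band_power(des, 200, 0.5, 4))
  expect_gt(welch_band_power(nrem, 200, 9, 16), 2 * welch_band_power(des, 200, 9, 16))
})

test_that("sampling rates below Nyquist for the requested content are rejected", {
  expect_error(synthetic_config(rate_hz = 100, ripple_rate_per_min = 2),
               "Nyquist")
  expect_error(synthetic_config(rate_hz = 100, line_noise_amp_uv = 5),
               "Nyquist")
  # no ripples or line noise: 100 Hz is fine for spindles at 13 Hz
  expect_s3_class(synthetic_config(rate_hz = 100, line_noise_amp_uv = 0),
                  "sleeploop_config")
})

test_that("spike trains follow the cosine-modulated Poisson model", {
  rate <- 100
  phase <- ((seq_len(600 * rate) - 1) / rate * 360) %% 360 - 180
  units <- tibble::tibble(unit_id = c("u0", "u1"), base_rate_hz = 5,
                          m = c(0, 1), phi0_deg = 0)
  tr <- generate_spike_trains(phase, rate, units, seed = 2)
  n0 <- sum(tr$unit_id == "u0"); n1 <- sum(tr$unit_id == "u1")
  # both units fire at the base rate on average regardless of modulation
  expect_gt(n0, 5 * 600 * 0.85); expect_lt(n0, 5 * 600 * 1.15)
  expect_gt(n1, 5 * 600 * 0.85); expect_lt(n1, 5 * 600 * 1.15)
  # the fully modulated unit concentrates spikes near its preferred phase
  ph1 <- phase[round(tr$time_s[tr$unit_id == "u1"] * rate) + 1]
  expect_gt(mean(abs(ph1) < 90), 0.75)
  expect_identical(tr, generate_spike_trains(phase, rate, units, seed = 2))
  expect_error(generate_spike_trains(phase, rate,
                 tibble::tibble(unit_id = "x", base_rate_hz = 1, m = 1.2, phi0_deg = 0)),
               "m must lie")
})

test_that("behavioral generator matches its Bernoulli design", {
  s <- generate_behavioral_responses(1, 0, seed = 1)
  expect_equal(recognition_accuracy(s)$accuracy, 1)
  # expected accuracy p_hit - p_fa, checked over many seeded sessions
  accs <- vapply(1:400, function(i) {
    recognition_accuracy(generate_behavioral_responses(0.8, 0.2, seed = i))$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.6), 0.02)
  expect_error(generate_behavioral_responses(1.2, 0), "probabilities")
})
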