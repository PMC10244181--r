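two_block_log <- function(stim_times, peak_times) {
  make_stimlog(stim_times, peak_times,
               tibble::tibble(start_s = c(0, 60), end_s = c(60, 120),
                              kind = c("STIM", "PAUSE")))
}

test_that("sham events replicate stimulation delays onto pause-block peaks", {
  lg <- two_block_log(10.2, 10.0)
  sh <- generate_sham_events(lg, 100, seed = 1)
  expect_equal(sh$time_s, 100.2)
  # zero stims -> zero shams
  lg0 <- two_block_log(numeric(0), numeric(0))
  expect_equal(nrow(generate_sham_events(lg0, 100, seed = 1)), 0)
  # counts always match and fixed seeds reproduce the set
  lg3 <- two_block_log(c(10.2, 20.3, 30.25), c(10, 20, 30))
  sh3 <- generate_sham_events(lg3, seq(61, 119, by = 7), seed = 5)
  expect_equal(nrow(sh3), 3)
  expect_identical(sh3, generate_sham_events(lg3, seq(61, 119, by = 7), seed = 5))
  expect_error(generate_sham_events(lg3, numeric(0), seed = 1), "no pause-block")
})

test_that("sham construction resamples with replacement when peaks are scarce", {
  lg3 <- two_block_log(c(10.2, 20.3, 30.25), c(10, 20, 30))
  expect_message(sh <- generate_sham_events(lg3, c(90), seed = 2), "replacement")
  expect_equal(nrow(sh), 3)
  expect_true(all(sh$source_peak_s == 90))
})

test_that("event probability counts detections per trigger", {
  trig <- seq(10, 100, by = 10)
  ev <- trig[1:4] + 1  # four triggers followed by one event each
  p <- event_probability(ev, trig, 3)
  expect_equal(p$probability, 0.4)
  expect_equal(p$frac_triggers_with_event, 0.4)
  expect_equal(event_probability(numeric(0), trig, 3)$probability, 0)
  expect_equal(event_probability(trig + 1, trig, 3)$probability, 1)
  expect_error(event_probability(ev, numeric(0)), "no triggers")
})

test_that("contrast indices follow (A - B)/(A + B) with exclusion at 0/0", {
  expect_equal(immediate_contrast(0.2, 0.1)$value, 1 / 3)
  expect_equal(immediate_contrast(0.37, 0.37)$value, 0)
  expect_equal(immediate_contrast(0.3, 0)$value, 1)
  expect_true(immediate_contrast(0, 0)$excluded)
  # antisymmetry and bounds on random pairs
  set.seed(1)
  a <- runif(50); b <- runif(50)
  expect_equal(contrast_index(a, b), -contrast_index(b, a))
  expect_true(all(abs(contrast_index(a, b)) <= 1))
})

test_that("prolonged enhancement pools 1-min post-block and pre-next-block windows", {
  blocks <- tibble::tibble(start_s = c(0, 300, 600), end_s = c(300, 600, 900),
                           kind = c("STIM", "PAUSE", "STIM"))
  # 12 events in [300, 360), 8 in [540, 600)
  ev <- c(seq(301, 359, length.out = 12), seq(541, 599, length.out = 8))
  pe <- prolonged_enhancement(ev, blocks)
  expect_equal(pe$value, (12 - 8) / (12 + 8))
  expect_equal(pe$rate_post_per_min, 12)
  # equal rates -> 0; post-only -> 1
  pe0 <- prolonged_enhancement(c(seq(301, 359, length.out = 5),
                                 seq(541, 599, length.out = 5)), blocks)
  expect_equal(pe0$value, 0)
  pe1 <- prolonged_enhancement(seq(301, 359, length.out = 5), blocks)
  expect_equal(pe1$value, 1)
  expect_error(prolonged_enhancement(ev, blocks[1:2, ]), "complete")
})

test_that("slow-wave/spindle sequences respect the 1.5-s forward window", {
  sw <- tibble::tibble(peak_s = c(10, 20))
  sp <- tibble::tibble(peak_s = c(11, 21.6, 19.5), is_fast = TRUE)
  seqs <- sw_spindle_sequences(sw, sp)
  expect_equal(nrow(seqs), 1)
  expect_equal(seqs$sw_peak_s, 10)
  expect_equal(seqs$spindle_peak_s, 11)
  # spindles before the peak or beyond 1.5 s do not pair
  expect_equal(nrow(sw_spindle_sequences(sw, tibble::tibble(peak_s = 9.5))), 0)
  # fast-only filtering drops slow spindles
  sp2 <- tibble::tibble(peak_s = c(11, 20.5), is_fast = c(FALSE, TRUE))
  expect_equal(nrow(sw_spindle_sequences(sw, sp2, fast_only = TRUE)), 1)
})

test_that("ripple/slow-wave couples use the 50-400 ms distance and window gating", {
  rip <- tibble::tibble(peak_s = c(10.0, 30.0))
  sw <- tibble::tibble(peak_s = c(10.2, 30.01, seq(100, 130, by = 2)))
  win <- tibble::tibble(start_s = c(0, 100), end_s = c(60, 160))
  cc <- ripple_sw_cooccurrence(rip, sw, win)
  expect_equal(nrow(cc$couples), 1)          # 200 ms couples, 10 ms does not
  expect_equal(cc$couples$ripple_peak_s, 10.0)
  # the first window holds 2 slow waves (<= 10) -> excluded
  expect_true(cc$windows$excluded[1])
  expect_false(cc$windows$excluded[2])       # 16 slow waves
  expect_true(is.na(cc$windows$incidence_per_min[1]))
})

test_that("triples require the ripple to precede the sequence by 50-400 ms", {
  rip <- tibble::tibble(peak_s = c(10.0, 50.0))
  seqs <- tibble::tibble(sw_peak_s = c(10.2, 50.5), spindle_peak_s = c(11.0, 51.2))
  tri <- triple_cooccurrence(rip, seqs)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$sw_peak_s, 10.2)
  expect_equal(nrow(triple_cooccurrence(rip[0, ], seqs)), 0)
})

test_that("triple counts never exceed couple counts nor event counts", {
  set.seed(3)
  for (k in 1:20) {
    rip <- tibble::tibble(peak_s = sort(runif(15, 0, 300)))
    sw <- tibble::tibble(peak_s = sort(runif(40, 0, 300)))
    sp <- tibble::tibble(peak_s = sort(runif(25, 0, 300)), is_fast = TRUE)
    win <- tibble::tibble(start_s = 0, end_s = 300)
    seqs <- sw_spindle_sequences(sw, sp)
    cc <- ripple_sw_cooccurrence(rip, sw, win, signed = TRUE)
    tri <- triple_cooccurrence(rip, seqs)
    expect_lte(nrow(tri), nrow(cc$couples))
    expect_lte(nrow(cc$couples), min(nrow(rip), nrow(sw)))
    expect_lte(nrow(tri), min(nrow(rip), nrow(seqs)))
  }
})

test_that("the trigger-locked TFR localizes induced sigma power after the trigger", {
  rate <- 200
  set.seed(2)
  x <- sleeploop:::colored_noise(rate * 300, 1.5) * 10
  trig <- seq(20, 280, by = 10)
  x2 <- x
  for (tt in trig) {
    i <- round((tt + 0.5) * rate):round((tt + 1.5) * rate)
    x2[i] <- x2[i] + 25 * sin(2 * pi * 12 * i / rate) * sleeploop:::tukey_env(length(i))
  }
  tfr <- stim_locked_tfr(x2, rate, trig)
  expect_gt(tfr_band_change(tfr, c(9, 16), c(0.4, 1.6)), 100)
  expect_lt(abs(tfr_band_change(tfr, c(9, 16), c(-1, -0.1))), 25)
  # stationary noise: no systematic change anywhere
  tfr0 <- stim_locked_tfr(x, rate, trig)
  expect_lt(abs(tfr_band_change(tfr0, c(9, 16), c(0, 2.5))), 25)
  expect_error(stim_locked_tfr(x, rate, numeric(0)), "no usable triggers")
  # tidy() long format matches the matrix
  td <- tidy(tfr)
  expect_equal(nrow(td), length(tfr$freq_hz) * length(tfr$time_s))
})

test_that("sham-controlled contrast is near zero when spindles ignore stimulation", {
  # one decoupled session; the full 50-session calibration runs in acceptance
  cfg <- synthetic_config(duration_s = 600, rate_hz = 200, seed = 61,
                          spindle_coupling_prob = 0, spindle_rate_per_min = 6)
  out <- generate_recording(cfg)
  x <- channel_signal(out$recording, 1)
  lg <- run_closed_loop(x, 200, stim_protocol(initial_delay_ms = 330,
                                              block_s = 120, pause_s = 120), seed = 61)
  cand <- detect_slow_waves(x, 200, amplitude_criterion = FALSE)
  pause_ok <- vapply(cand$peak_s, function(p) {
    any(lg$blocks$kind == "PAUSE" & lg$blocks$start_s <= p & p < lg$blocks$end_s)
  }, logical(1))
  sham <- generate_sham_events(lg, cand$peak_s[pause_ok], seed = 61)
  expect_equal(nrow(sham), nrow(lg$stims))
  sp <- detect_spindles(x, 200)
  v <- contrast_index(event_probability(sp$peak_s, lg$stims$time_s, 3)$probability,
                      event_probability(sp$peak_s, sham$time_s, 3)$probability)
  expect_lt(abs(v), 0.6)  # a single session is noisy but bounded
})

test_that("the random sham policy draws uniformly over pause blocks", {
  lg <- make_stimlog(c(10.2, 20.3), c(10, 20),
                     tibble::tibble(start_s = c(0, 60, 120, 180),
                                    end_s = c(60, 120, 180, 240),
                                    kind = c("STIM", "PAUSE", "STIM", "PAUSE")))
  sh <- generate_sham_events(lg, numeric(0), seed = 3, policy = "random",
                             n_random = 500)
  expect_equal(nrow(sh), 500)
  in_pause <- (sh$time_s >= 60 & sh$time_s < 120) |
    (sh$time_s >= 180 & sh$time_s < 240)
  expect_true(all(in_pause))
  expect_identical(sh, generate_sham_events(lg, numeric(0), seed = 3,
                                            policy = "random", n_random = 500))
})

test_that("participant scores are medians over evaluable channels", {
  expect_equal(participant_enhancement_score(c(0.2, -0.1, NA, 0.4)), 0.2)
  expect_true(is.na(participant_enhancement_score(c(NA, NA))))
})
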