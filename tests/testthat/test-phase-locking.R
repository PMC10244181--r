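test_that("the phase convention puts 0 at peaks and +/-180 at troughs", {
  rate <- 200
  t <- (0:(rate * 60 - 1)) / rate
  x <- 50 * cos(2 * pi * 1 * t)
  ph <- slow_wave_phase(x, rate)
  mid <- (rate * 10):(rate * 50)
  # 0 degrees at peaks (integer seconds), +/-180 at troughs
  peaks <- mid[abs(t[mid] %% 1) < 1e-9]
  expect_true(all(abs(ph[peaks]) < 5))
  troughs <- mid[abs(t[mid] %% 1 - 0.5) < 1e-9]
  expect_true(all(abs(ph[troughs]) > 175))
  # negation shifts the phase by 180 degrees
  ph_neg <- slow_wave_phase(-x, rate)
  d <- abs(sleeploop:::deg_wrap(ph_neg[mid] - ph[mid]))
  expect_true(all(abs(d - 180) < 5))
  # phase increases with time
  expect_gt(mean(diff(ph[mid]) > 0), 0.95)
  expect_error(slow_wave_phase(x[1:100], rate), "too short")
})

test_that("generated slow-wave troughs map to the active (+/-180) phase", {
  out <- fixture_full(11)
  x <- channel_signal(out$recording, 1)
  ph <- slow_wave_phase(x, 400)
  troughs <- out$truth$events$trough_s[out$truth$events$kind == "slow_wave"]
  ph_tr <- ph[round(troughs * 400) + 1]
  expect_gt(mean(abs(ph_tr) > 120), 0.9)
})

test_that("a noiseless cosine histogram is recovered exactly", {
  centers <- seq(-170, 170, by = 20)
  y <- 10 * cos((centers + 30) * pi / 180) + 20
  fit <- sleeploop:::cosine_ls_fit(centers, y)
  expect_equal(fit$a, 10, tolerance = 1e-10)
  expect_equal(fit$b, 30, tolerance = 1e-10)
  expect_equal(fit$c, 20, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(2 * fit$a / (2 * fit$a + fit$c), 0.5)
})

test_that("the closed-form fit matches a 1-degree-grid brute-force oracle", {
  brute_force <- function(phi, y) {
    best <- NULL
    for (b in seq(-180, 179)) {
      X <- cbind(cos((phi + b) * pi / 180), 1)
      beta <- stats::lm.fit(X, y)$coefficients
      rss <- sum((y - X %*% beta)^2)
      if (is.null(best) || rss < best$rss) {
        a <- beta[1]; bb <- b
        if (a < 0) { a <- -a; bb <- sleeploop:::deg_wrap(b + 180) }
        best <- list(a = unname(a), b = bb, c = unname(beta[2]), rss = rss)
      }
    }
    best
  }
  centers <- seq(-170, 170, by = 20)
  set.seed(12)
  for (k in 1:5) {
    b_true <- sample(-179:179, 1)  # on-grid optimum
    y <- 8 * cos((centers + b_true) * pi / 180) + 15
    ls <- sleeploop:::cosine_ls_fit(centers, y)
    bf <- brute_force(centers, y)
    expect_equal(ls$a, bf$a, tolerance = 1e-6)
    expect_equal(ls$c, bf$c, tolerance = 1e-6)
    expect_equal(sleeploop:::deg_wrap(ls$b - bf$b), 0, tolerance = 1e-6)
  }
  # with noise the closed form can only do better than the 1-degree grid
  y2 <- 8 * cos((centers + 37.3) * pi / 180) + 15 + rnorm(18)
  ls2 <- sleeploop:::cosine_ls_fit(centers, y2)
  bf2 <- brute_force(centers, y2)
  rss_ls <- sum((y2 - (ls2$a * cos((centers + ls2$b) * pi / 180) + ls2$c))^2)
  expect_lte(rss_ls, bf2$rss * (1 + 1e-9))
})

test_that("locking depth recovers 2m/(2m+1) from generated spike trains", {
  rate <- 100
  phase <- ((0:(1800 * rate - 1)) / rate * 360) %% 360 - 180
  for (m in c(0.25, 1)) {
    tr <- generate_spike_trains(phase, rate,
            tibble::tibble(unit_id = "u", base_rate_hz = 8, m = m, phi0_deg = 60),
            seed = 17 + round(100 * m))
    f <- fit_spike_phase_cosine(tr$time_s, phase, rate)
    expect_lt(abs(f$ld - 2 * m / (2 * m + 1)), 0.05)
    expect_true(f$significant)
    expect_lt(abs(sleeploop:::deg_wrap(f$pref_phase_deg - 60)), 15)
  }
})

test_that("uniform phases give near-zero locking and a null Rayleigh test", {
  set.seed(5)
  rate <- 100
  phase <- ((0:(1800 * rate - 1)) / rate * 360) %% 360 - 180
  tr <- generate_spike_trains(phase, rate,
          tibble::tibble(unit_id = "u", base_rate_hz = 8, m = 0, phi0_deg = 0),
          seed = 23)
  f <- fit_spike_phase_cosine(tr$time_s, phase, rate)
  expect_lt(f$ld, 0.08)
  expect_gt(f$rayleigh_p, 0.01)
  # the LD index is invariant to a uniform rescaling of the histogram
  centers <- seq(-170, 170, by = 20)
  y <- 5 * cos((centers - 10) * pi / 180) + 12
  f1 <- sleeploop:::cosine_ls_fit(centers, y)
  f2 <- sleeploop:::cosine_ls_fit(centers, 10 * y)
  expect_equal(2 * f1$a / (2 * f1$a + f1$c), 2 * f2$a / (2 * f2$a + f2$c))
})

test_that("rate and spike-count gates mark units unevaluable", {
  rate <- 100
  phase <- rep(0, rate * 100)
  f <- fit_spike_phase_cosine(seq(1, 5, length.out = 10), phase, rate)
  expect_false(f$evaluable)
  # rate below 0.1 Hz: 20 spikes in 1000 s
  phase2 <- rep(0, rate * 1000)
  f2 <- fit_spike_phase_cosine(seq(1, 999, length.out = 20), phase2, rate)
  expect_false(f2$evaluable)
  expect_true(is.na(f2$ld))
})

test_that("spikes within 500 ms after stimulations are excluded from fits", {
  rate <- 100
  phase <- ((0:(600 * rate - 1)) / rate * 360) %% 360 - 180
  spikes <- seq(10, 590, by = 1)
  stims <- seq(20, 580, by = 20)
  f_all <- fit_spike_phase_cosine(spikes, phase, rate)
  f_exc <- fit_spike_phase_cosine(spikes, phase, rate, exclude_after_s = stims)
  # one spike sits 0.0 < dt <= 0.5 after 29 stims... those spikes are gone
  dropped <- sum(vapply(spikes, function(t) any(t > stims & t <= stims + 0.5), TRUE))
  expect_equal(f_all$n_spikes - f_exc$n_spikes, dropped)
})

test_that("locking-depth change follows the contrast form with significance gating", {
  expect_equal(lock_depth_change(0.6, 0.4), 0.2, tolerance = 1e-12)
  expect_equal(lock_depth_change(0.37, 0.37), 0)
  expect_equal(lock_depth_change(0.5, 0), 1)
  sig <- structure(list(ld = 0.5, evaluable = TRUE, significant = TRUE),
                   class = "sleeploop_plfit")
  nonsig <- structure(list(ld = 0.3, evaluable = TRUE, significant = FALSE),
                      class = "sleeploop_plfit")
  expect_equal(lock_depth_change(sig, sig), 0)
  expect_true(is.na(lock_depth_change(sig, nonsig)))
  expect_equal(lock_depth_change(sig, nonsig, require_significant = FALSE), 0.25)
})

test_that("label shuffling yields calibrated permutation p-values", {
  set.seed(8)
  a <- runif(20, 0.4, 0.6)
  p_same <- label_shuffle_null(a, a, n_perm = 500, seed = 1)
  expect_equal(p_same$observed, 0)
  expect_gt(p_same$p_value, 0.5)
  b <- runif(20, 0.05, 0.15)
  p_diff <- label_shuffle_null(a, b, n_perm = 2000, seed = 1)
  expect_lt(p_diff$p_value, 0.01)
  expect_identical(label_shuffle_null(a, b, n_perm = 500, seed = 9),
                   label_shuffle_null(a, b, n_perm = 500, seed = 9))
  expect_warning(p_small <- label_shuffle_null(a[1:3], b[1:3]), "enumerating")
  expect_equal(p_small$n_perm, 8)
})

test_that("rate-matched subsampling is centered and consistent with the full fit", {
  rate <- 100
  phase <- ((0:(1200 * rate - 1)) / rate * 360) %% 360 - 180
  tr_hi <- generate_spike_trains(phase, rate,
             tibble::tibble(unit_id = "u", base_rate_hz = 6, m = 0.8, phi0_deg = 0),
             seed = 31)
  tr_lo <- generate_spike_trains(phase, rate,
             tibble::tibble(unit_id = "u", base_rate_hz = 6, m = 0.2, phi0_deg = 0),
             seed = 32)
  same <- rate_matched_subsample(tr_hi$time_s, tr_hi$time_s, phase, rate,
                                 n_rep = 60, seed = 1)
  expect_lt(abs(mean(same$changes)), 0.03)
  expect_equal(same$n_subsample, floor(0.9 * nrow(tr_hi)))
  diff <- rate_matched_subsample(tr_hi$time_s, tr_lo$time_s, phase, rate,
                                 n_rep = 60, seed = 1)
  expect_gt(mean(diff$changes), 0.2)
  expect_gt(diff$full_change, 0.2)
  expect_lt(abs(mean(diff$changes) - diff$full_change), 0.1)
  few <- rate_matched_subsample(1:10, 1:10, phase, rate)
  expect_false(few$evaluable)
})

test_that("histograms with a good cosine fit are almost always Rayleigh significant", {
  rate <- 50
  phase <- ((0:(1800 * rate - 1)) / rate * 360) %% 360 - 180
  set.seed(77)
  n_good <- 0; n_sig <- 0
  for (k in 1:40) {
    m <- runif(1, 0.1, 0.6)
    tr <- generate_spike_trains(phase, rate,
            tibble::tibble(unit_id = "u", base_rate_hz = 0.35, m = m, phi0_deg = 0),
            seed = 1000 + k)
    f <- fit_spike_phase_cosine(tr$time_s, phase, rate)
    if (isTRUE(f$evaluable) && isTRUE(f$good_fit)) {
      n_good <- n_good + 1
      n_sig <- n_sig + isTRUE(f$significant)
    }
  }
  expect_gt(n_good, 5)
  expect_gte(n_sig / n_good, 0.9)
})
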