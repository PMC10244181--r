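# Spike-field phase locking: slow-wave phase extraction, cosine fits of
# spike-phase histograms, locking-depth contrasts, and the two shuffling
# validations (label permutation and rate-matched subsampling).

#' Instantaneous slow-wave phase of an MTL probe signal
#'
#' Zero-phase Butterworth band-pass (0.5-2 Hz by default) followed by the
#' Hilbert transform. Convention: 0 degrees at the filtered-signal positive
#' peak (inactive/OFF phase), +/-180 degrees at the trough (active/ON
#' phase), phase increasing with time; values lie in [-180, 180).
#'
#' @param x numeric signal, microvolts.
#' @param rate_hz sampling rate.
#' @param band band edges in Hz (default `c(0.5, 2)`; the online controller
#'   band 0.5-4 Hz is also accepted).
#' @param order Butterworth order (default 2).
#' @return numeric vector of per-sample phase, degrees.
#' @export
slow_wave_phase <- function(x, rate_hz, band = c(0.5, 2), order = 2L) {
  if (length(x) < rate_hz / band[1] * 2) {
    stop("signal too short: need at least two cycles of the low band edge", call. = FALSE)
  }
  filt <- butter_bandpass(x, rate_hz, band[1], band[2], order = order)
  deg_wrap(Arg(analytic_signal(filt)) * 180 / pi)
}

# Closed-form least-squares fit of a*cos(phi + b) + c to (phi, y):
# a*cos(phi + b) = A*cos(phi) + B*sin(phi) with A = a cos b, B = -a sin b.
cosine_ls_fit <- function(phi_deg, y) {
  ph <- phi_deg * pi / 180
  X <- cbind(cos(ph), sin(ph), 1)
  beta <- stats::lm.fit(X, y)$coefficients
  a <- sqrt(beta[1]^2 + beta[2]^2)
  b <- deg_wrap(atan2(-beta[2], beta[1]) * 180 / pi)
  c0 <- beta[3]
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2); ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(a = unname(a), b = unname(b), c = unname(c0), r2 = unname(r2))
}

#' Rayleigh test for circular non-uniformity
#'
#' @param phi_deg phases in degrees.
#' @return list with `r_bar` (resultant length) and `p_value` (Zar's
#'   approximation to the Rayleigh p).
#' @export
rayleigh_test <- function(phi_deg) {
  n <- length(phi_deg)
  ph <- phi_deg * pi / 180
  r_bar <- Mod(mean(exp(1i * ph)))
  z <- n * r_bar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (r_bar * n)^2)) - (1 + 2 * n))
  list(r_bar = r_bar, p_value = min(1, p))
}

#' Fit a cosine to a spike-phase histogram and compute locking depth
#'
#' Spike phases (sampled from a per-sample phase series at each spike time,
#' restricted to an optional condition mask) are binned into 18 20-degree
#' bins over [-180, 180) and the histogram fitted with
#' `f(phi) = a*cos(phi + b) + c` by closed-form linear least squares (exact
#' global optimum; the sign convention keeps `a >= 0`). Locking depth is
#' `LD = 2a / (2a + c)`. The Rayleigh test runs on the raw (unbinned)
#' phases. Units firing below `min_rate_hz` within the condition, or with
#' fewer than 18 spikes, are unevaluable.
#'
#' @param spike_times_s spike timestamps, seconds.
#' @param phase_deg per-sample phase series (degrees), e.g. from
#'   [slow_wave_phase()].
#' @param rate_hz sampling rate of `phase_deg`.
#' @param condition_mask optional logical per-sample mask restricting the
#'   condition (spikes outside it are dropped; the condition duration is
#'   the mask's total time).
#' @param exclude_after_s optional timestamps (e.g. stimulations): spikes
#'   within `exclude_window_s` after any of them are excluded.
#' @param exclude_window_s exclusion window, seconds (default 0.5).
#' @param min_rate_hz minimum mean firing rate within the condition
#'   (default 0.1).
#' @param condition condition label stored in the result.
#' @return object of class `sleeploop_plfit`: list with `a`, `b`, `c`,
#'   `r2`, `ld`, `rayleigh_p`, `n_spikes`, `mean_rate_hz`, `significant`
#'   (Rayleigh p < 0.05), `good_fit` (r2 > 0.25), `pref_phase_deg`,
#'   `phase_category` (`"ON"` if the preferred phase is within 90 degrees
#'   of the trough at +/-180, else `"OFF"`), `evaluable`, `condition`.
#' @export
fit_spike_phase_cosine <- function(spike_times_s, phase_deg, rate_hz,
                                   condition_mask = NULL,
                                   exclude_after_s = NULL,
                                   exclude_window_s = 0.5,
                                   min_rate_hz = 0.1,
                                   condition = "all") {
  n <- length(phase_deg)
  if (is.null(condition_mask)) condition_mask <- rep(TRUE, n)
  spikes <- spike_times_s
  if (!is.null(exclude_after_s) && length(exclude_after_s)) {
    drop <- vapply(spikes, function(t) {
      any(t > exclude_after_s & t <= exclude_after_s + exclude_window_s)
    }, logical(1))
    spikes <- spikes[!drop]
  }
  idx <- time_to_index(spikes, rate_hz, n)
  keep <- condition_mask[idx] & spikes < n / rate_hz & spikes >= 0
  spikes <- spikes[keep]; idx <- idx[keep]
  dur <- sum(condition_mask) / rate_hz
  mean_rate <- length(spikes) / dur
  base <- list(condition = condition, n_spikes = length(spikes),
               mean_rate_hz = mean_rate)
  if (length(spikes) < 18L || mean_rate < min_rate_hz) {
    out <- c(base, list(a = NA_real_, b = NA_real_, c = NA_real_, r2 = NA_real_,
                        ld = NA_real_, rayleigh_p = NA_real_, significant = NA,
                        good_fit = NA, pref_phase_deg = NA_real_,
                        phase_category = NA_character_, evaluable = FALSE))
    class(out) <- "sleeploop_plfit"
    return(out)
  }
  ph <- phase_deg[idx]
  edges <- seq(-180, 180, by = 20)
  counts <- as.numeric(table(cut(ph, breaks = edges, right = FALSE,
                                 include.lowest = FALSE)))
  centers <- edges[-length(edges)] + 10
  fit <- cosine_ls_fit(centers, counts)
  ld <- 2 * fit$a / (2 * fit$a + fit$c)
  ray <- rayleigh_test(ph)
  pref <- deg_wrap(-fit$b)  # f is maximal at phi = -b
  out <- c(base, list(a = fit$a, b = fit$b, c = fit$c, r2 = fit$r2, ld = ld,
                      rayleigh_p = ray$p_value,
                      significant = ray$p_value < 0.05,
                      good_fit = !is.na(fit$r2) && fit$r2 > 0.25,
                      pref_phase_deg = pref,
                      phase_category = if (abs(pref) >= 90) "ON" else "OFF",
                      evaluable = TRUE))
  class(out) <- "sleeploop_plfit"
  out
}

#' @export
print.sleeploop_plfit <- function(x, ...) {
  if (!x$evaluable) {
    cat("<sleeploop_plfit> unevaluable (", x$n_spikes, " spikes, ",
        signif(x$mean_rate_hz, 3), " Hz)\n", sep = "")
  } else {
    cat(sprintf("<sleeploop_plfit> LD = %.3f (a = %.2f, b = %.1f deg, c = %.2f), R2 = %.3f, Rayleigh p = %.2g, n = %d\n",
                x$ld, x$a, x$b, x$c, x$r2, x$rayleigh_p, x$n_spikes))
  }
  invisible(x)
}

#' Locking-depth change index between two conditions
#'
#' `(LD_condition - LD_baseline) / (LD_condition + LD_baseline)`, defined
#' for units with significant phase locking in both conditions.
#'
#' @param fit_condition,fit_baseline `sleeploop_plfit` objects, or bare LD
#'   values.
#' @param require_significant require Rayleigh p < 0.05 in both fits when
#'   fit objects are given (default TRUE).
#' @return the change index, or `NA` when excluded.
#' @export
lock_depth_change <- function(fit_condition, fit_baseline,
                              require_significant = TRUE) {
  get_ld <- function(f) {
    if (inherits(f, "sleeploop_plfit")) {
      if (!isTRUE(f$evaluable)) return(NA_real_)
      if (require_significant && !isTRUE(f$significant)) return(NA_real_)
      f$ld
    } else as.numeric(f)
  }
  ld1 <- get_ld(fit_condition); ld0 <- get_ld(fit_baseline)
  if (is.na(ld1) || is.na(ld0)) return(NA_real_)
  contrast_index(ld1, ld0)
}

#' Permutation null for a population locking-depth change
#'
#' Within each unit the two conditions' LD values are swapped at random
#' (condition labels reassigned), and the mean change index recomputed;
#' the two-sided p-value is the fraction of permuted means at least as
#' extreme as the observed one. With fewer than 5 pairs all `2^n` label
#' assignments are enumerated exactly (with a warning).
#'
#' @param ld_a,ld_b paired LD vectors (condition and baseline).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `observed` (mean change index), `p_value`, `n_perm`.
#' @export
label_shuffle_null <- function(ld_a, ld_b, n_perm = 10000, seed = 1L) {
  stopifnot(length(ld_a) == length(ld_b))
  ok <- !(is.na(ld_a) | is.na(ld_b))
  ld_a <- ld_a[ok]; ld_b <- ld_b[ok]
  n <- length(ld_a)
  stat <- function(a, b) mean(contrast_index(a, b), na.rm = TRUE)
  obs <- stat(ld_a, ld_b)
  if (n < 5L) {
    warning("fewer than 5 pairs; enumerating all label assignments exactly")
    flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    perm <- apply(flips, 1, function(fl) {
      a <- ifelse(fl, ld_b, ld_a); b <- ifelse(fl, ld_a, ld_b)
      stat(a, b)
    })
    p <- mean(abs(perm) >= abs(obs) - 1e-12)
    return(list(observed = obs, p_value = p, n_perm = nrow(flips)))
  }
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    fl <- stats::runif(n) < 0.5
    a <- ifelse(fl, ld_b, ld_a); b <- ifelse(fl, ld_a, ld_b)
    stat(a, b)
  }, 0)
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
  list(observed = obs, p_value = p, n_perm = n_perm)
}

#' Rate-matched subsampling control for a locking-depth change
#'
#' To rule out firing-rate differences biasing the locking-depth change,
#' `X = floor(0.9 * min(nA, nB))` spikes are drawn without replacement from
#' each condition, the cosine fits recomputed, and the change index
#' recorded, `n_rep` times. The full-spike estimate and a Wilcoxon
#' signed-rank comparison of the subsampled distribution against it are
#' returned.
#'
#' @param spikes_a,spikes_b spike time vectors for the two conditions.
#' @param phase_deg,rate_hz phase series and its sampling rate.
#' @param mask_a,mask_b optional condition masks (passed through to the
#'   fits).
#' @param n_rep repetitions (default 1000).
#' @param seed integer seed.
#' @return list with `changes` (numeric vector of subsampled change
#'   indices), `full_change` (full-spike estimate), `n_subsample`,
#'   `wilcoxon_p` (subsampled distribution vs the full estimate), and
#'   `evaluable`.
#' @export
rate_matched_subsample <- function(spikes_a, spikes_b, phase_deg, rate_hz,
                                   mask_a = NULL, mask_b = NULL,
                                   n_rep = 1000, seed = 1L) {
  x_n <- floor(0.9 * min(length(spikes_a), length(spikes_b)))
  if (x_n < 18L) {
    return(list(changes = numeric(0), full_change = NA_real_,
                n_subsample = x_n, wilcoxon_p = NA_real_, evaluable = FALSE))
  }
  fit_ld <- function(sp, msk) {
    f <- fit_spike_phase_cosine(sp, phase_deg, rate_hz, condition_mask = msk)
    if (isTRUE(f$evaluable)) f$ld else NA_real_
  }
  full <- contrast_index(fit_ld(spikes_a, mask_a), fit_ld(spikes_b, mask_b))
  set.seed(seed)
  changes <- vapply(seq_len(n_rep), function(i) {
    sa <- sample(spikes_a, x_n); sb <- sample(spikes_b, x_n)
    contrast_index(fit_ld(sa, mask_a), fit_ld(sb, mask_b))
  }, 0)
  wp <- tryCatch(stats::wilcox.test(changes - full)$p.value, error = function(e) NA_real_)
  list(changes = changes, full_change = full, n_subsample = x_n,
       wilcoxon_p = wp, evaluable = TRUE)
}
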