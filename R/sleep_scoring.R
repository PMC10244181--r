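#' Slow-wave and sigma band power per 30-s epoch
#'
#' Short-time Fourier power (30-s windows, no overlap) averaged over the
#' slow-wave (0.5-4 Hz) and sigma/spindle (9-16 Hz) bands — the two joint
#' features the NREM scorer clusters. Epochs with more than half their
#' samples masked out are returned as missing; lesser masked stretches are
#' linearly interpolated before the transform.
#'
#' @param x numeric signal vector, microvolts.
#' @param rate_hz sampling rate.
#' @param valid_mask logical per-sample validity mask (default all TRUE).
#' @param epoch_s epoch length, seconds (default 30).
#' @return tibble with columns `epoch`, `epoch_start_s`, `sw_power`,
#'   `sigma_power` (power density, NA where missing).
#' @export
band_power_series <- function(x, rate_hz, valid_mask = NULL, epoch_s = 30) {
  n <- length(x)
  nseg <- floor(epoch_s * rate_hz)
  k <- floor(n / nseg)
  if (k < 1L) stop("recording shorter than one scoring epoch", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  freqs <- seq(0, rate_hz / 2, by = 1 / epoch_s)
  sw_sel <- freqs >= 0.5 & freqs <= 4
  sig_sel <- freqs >= 9 & freqs <= 16
  sw <- sig <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    idx <- ((i - 1L) * nseg + 1L):(i * nseg)
    m <- valid_mask[idx]
    if (mean(m) < 0.5) next
    seg <- x[idx]
    if (!all(m)) {
      seg[!m] <- NA
      seg <- stats::approx(which(!is.na(seg)), seg[!is.na(seg)], xout = seq_along(seg),
                           rule = 2)$y
    }
    seg <- seg - mean(seg)
    p <- Mod(stats::fft(seg))^2 / (nseg * rate_hz)
    p <- p[seq_along(freqs)]
    sw[i] <- mean(p[sw_sel])
    sig[i] <- mean(p[sig_sel])
  }
  tibble::tibble(epoch = seq_len(k),
                 epoch_start_s = (seq_len(k) - 1L) * epoch_s,
                 sw_power = sw, sigma_power = sig)
}

#' Score NREM vs desynchronized epochs by a two-component Gaussian mixture
#'
#' Fits a two-component full-covariance Gaussian mixture to the joint
#' (log10 slow-wave power, log10 sigma power) vectors and labels each epoch
#' by its maximal posterior probability. The component with the higher mean
#' summed log band power is NREM. Powers are log-transformed before fitting
#' (band power is approximately log-normal), which also makes the labels
#' invariant to a common positive rescaling of the signal.
#'
#' @param powers a [band_power_series()] tibble.
#' @param seed integer seed (the mixture fit is deterministic; the seed is
#'   fixed for any tie-breaking randomness in the backend).
#' @return a hypnogram tibble: `epoch`, `epoch_start_s`, `label`
#'   (`"NREM"`/`"DESYNC"`, NA for missing epochs), `posterior_nrem`.
#' @export
score_nrem <- function(powers, seed = 1L) {
  ok <- stats::complete.cases(powers[, c("sw_power", "sigma_power")]) &
    powers$sw_power > 0 & powers$sigma_power > 0
  if (sum(ok) < 10L) stop("need at least 10 non-missing epochs to fit the mixture", call. = FALSE)
  xy <- cbind(log10(powers$sw_power[ok]), log10(powers$sigma_power[ok]))
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller's frame
  bic <- tryCatch(
    mclust::mclustBIC(xy, G = 1:2, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(bic) || anyNA(bic[, "VVV"]) || bic["1", "VVV"] >= bic["2", "VVV"]) {
    stop("mixture fit collapsed to a single cluster (one component fits the ",
         "band powers at least as well); review the recording manually",
         call. = FALSE)
  }
  fit <- tryCatch(
    mclust::Mclust(xy, G = 2, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$G != 2) {
    stop("mixture fit collapsed to a single cluster; review the recording manually",
         call. = FALSE)
  }
  means <- colSums(fit$parameters$mean)  # summed mean log band power per component
  nrem_comp <- which.max(means)
  post <- fit$z[, nrem_comp]
  # single-cluster data: the two forced components overlap and most epochs
  # are ambiguous rather than committed to one component
  ambiguous <- mean(abs(post - 0.5) < 0.3)
  if (abs(diff(means)) < 1e-9 || ambiguous > 0.5) {
    stop("mixture collapsed to a single cluster (components indistinguishable); ",
         "review the recording manually", call. = FALSE)
  }
  out <- tibble::tibble(epoch = powers$epoch,
                        epoch_start_s = powers$epoch_start_s,
                        label = NA_character_, posterior_nrem = NA_real_)
  out$posterior_nrem[ok] <- post
  out$label[ok] <- ifelse(post >= 0.5, "NREM", "DESYNC")
  out
}

#' Discard standalone NREM epochs far from any other NREM epoch
#'
#' A single isolated 30-s NREM detection whose nearest other NREM epoch is
#' more than 60 s away (strictly; a 60-s gap between epoch starts is kept)
#' is relabeled as desynchronized. All decisions are made against the input
#' labels simultaneously, which makes the operation idempotent.
#'
#' @param hypnogram a [score_nrem()] tibble.
#' @return the hypnogram with consolidated labels.
#' @export
consolidate <- function(hypnogram) {
  lab <- hypnogram$label
  nrem_idx <- which(!is.na(lab) & lab == "NREM")
  if (length(nrem_idx) < 2L) {
    drop <- nrem_idx  # a lone NREM epoch in the whole record is standalone
  } else {
    drop <- nrem_idx[vapply(nrem_idx, function(i) {
      d <- abs(hypnogram$epoch_start_s[i] - hypnogram$epoch_start_s[setdiff(nrem_idx, i)])
      min(d) > 60
    }, logical(1))]
  }
  lab[drop] <- "DESYNC"
  hypnogram$label <- lab
  hypnogram
}

#' Agreement between a hypnogram and a ground-truth state sequence
#'
#' @param hypnogram a [score_nrem()] tibble.
#' @param truth_epochs tibble with `epoch_start_s` and `state` (from the
#'   generator's ground truth).
#' @return fraction of scored epochs whose label matches the true state.
#' @export
hypnogram_agreement <- function(hypnogram, truth_epochs) {
  j <- dplyr::inner_join(hypnogram, truth_epochs, by = "epoch_start_s")
  j <- j[!is.na(j$label), , drop = FALSE]
  mean(j$label == j$state)
}
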