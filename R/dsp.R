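# Internal signal-processing primitives shared by the detectors and the
# closed-loop simulator. All functions operate on plain numeric vectors at a
# stated sampling rate; user-facing wrappers live in the module files.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x numeric vector.
#' @return complex vector, same length; `Mod()` is the instantaneous
#'   amplitude, `Arg()` the instantaneous phase in radians.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for the Hilbert transform", call. = FALSE)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Zero-phase FIR band-pass: Hamming-windowed linear-phase design applied
# forward and backward (two passes). FFT-based convolution keeps long
# low-frequency filters (tens of thousands of taps) tractable.
fir_bandpass <- function(x, rate_hz, low_hz, high_hz, order) {
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L  # even order -> symmetric, integer delay
  ny <- rate_hz / 2
  stopifnot(low_hz > 0, high_hz < ny, low_hz < high_hz)
  b <- signal::fir1(order, c(low_hz, high_hz) / ny, type = "pass")
  fir_filtfilt(b, x)
}

# Two-pass (zero-phase) filtering with an FIR given by taps b.
# Each pass pads by reflection and uses overlap-free FFT convolution.
fir_filtfilt <- function(b, x) {
  one_pass <- function(x) fir_causal(b, x, compensate = TRUE)
  rev(one_pass(rev(one_pass(x))))
}

# Causal FIR pass via FFT convolution. With compensate = TRUE the output is
# advanced by the filter's group delay (length(b)-1)/2 samples so that the
# result is time-aligned with the input; edges are reflection-padded.
fir_causal <- function(b, x, compensate = TRUE) {
  n <- length(x)
  nb <- length(b)
  pad <- min(n - 1L, nb)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  m <- length(xp) + nb - 1L
  nfft <- stats::nextn(m, 2)
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) *
                       stats::fft(c(b, numeric(nfft - nb))), inverse = TRUE)) / nfft
  delay <- if (compensate) (nb - 1L) %/% 2L else 0L
  y[(pad + 1L + delay):(pad + n + delay)]
}

# Zero-phase Butterworth band-pass (filtfilt), the convention used for
# spindle and phase extraction.
butter_bandpass <- function(x, rate_hz, low_hz, high_hz, order = 4L) {
  ny <- rate_hz / 2
  stopifnot(low_hz > 0, high_hz < ny)
  flt <- signal::butter(order, c(low_hz, high_hz) / ny, type = "pass")
  as.numeric(signal::filtfilt(flt, x))
}

butter_bandstop <- function(x, rate_hz, low_hz, high_hz, order = 2L) {
  ny <- rate_hz / 2
  flt <- signal::butter(order, c(low_hz, high_hz) / ny, type = "stop")
  as.numeric(signal::filtfilt(flt, x))
}

butter_highpass <- function(x, rate_hz, cutoff_hz, order = 4L) {
  ny <- rate_hz / 2
  stopifnot(cutoff_hz < ny)
  flt <- signal::butter(order, cutoff_hz / ny, type = "high")
  as.numeric(signal::filtfilt(flt, x))
}

# Centered moving average over an odd window of n samples (edges shrink).
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L) return(x)
  cs <- cumsum(c(0, x))
  half <- (n - 1L) %/% 2L
  len <- length(x)
  lo <- pmax(1L, seq_len(len) - half)
  hi <- pmin(len, seq_len(len) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Contiguous TRUE runs of a logical vector as a two-column matrix of
# first/last indices; zero-row matrix when none.
logical_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Welch-style band power: mean periodogram power density summed over
# [low_hz, high_hz] across non-overlapping segments of seg_s seconds.
welch_band_power <- function(x, rate_hz, low_hz, high_hz, seg_s = 4) {
  nseg <- floor(seg_s * rate_hz)
  k <- floor(length(x) / nseg)
  if (k < 1L) stop("signal shorter than one Welch segment", call. = FALSE)
  freqs <- seq(0, rate_hz / 2, by = rate_hz / nseg)
  sel <- freqs >= low_hz & freqs <= high_hz
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  pows <- vapply(seq_len(k), function(i) {
    seg <- x[((i - 1L) * nseg + 1L):(i * nseg)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (sum(w^2) * rate_hz)
    p <- p[seq_along(freqs)]
    mean(p[sel])
  }, numeric(1))
  mean(pows)
}

# Indices of interior local maxima (strictly greater than both neighbours,
# ties broken by >=) of a numeric vector.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# 1/f^a coloured noise of length n with unit standard deviation.
colored_noise <- function(n, exponent) {
  nf <- stats::nextn(n, 2)
  f <- c(1, seq_len(nf / 2), rev(seq_len(nf / 2 - 1L)))  # symmetric freq index
  amp <- f^(-exponent / 2)
  amp[1] <- 0
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  as.numeric(scale(x))
}

# Wrap degrees into [-180, 180), matching the left-closed histogram bins.
deg_wrap <- function(deg) {
  (deg + 180) %% 360 - 180
}
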