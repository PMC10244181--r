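#' Multichannel iEEG recording container
#'
#' A `sleeploop_recording` is a light S3 container for a uniformly sampled
#' multichannel signal: a channels-by-time numeric matrix in microvolts plus a
#' channel-metadata tibble. Every detector and the closed-loop simulator
#' consume either a whole recording or one channel extracted with
#' [channel_signal()].
#'
#' @param samples numeric matrix, channels in rows, samples in columns,
#'   microvolts.
#' @param rate_hz sampling rate in samples per second.
#' @param channels tibble with one row per channel. Recognised columns:
#'   `label` (unique, required), `region` (free-text region code, e.g.
#'   `"MTL"`, `"PFC"`), `hemisphere` (`"L"`/`"R"`), `tissue`
#'   (`"gray"`/`"white"`), `kind` (`"macro"`/`"micro"`), `electrode`
#'   (shaft identifier used for same-electrode comparisons). Missing columns
#'   are filled with `"unknown"`.
#' @param start_time_s clock offset of the first sample, seconds.
#'
#' @return An object of class `sleeploop_recording` with elements `samples`,
#'   `rate_hz`, `channels`, `start_time_s`.
#' @examples
#' rec <- new_recording(matrix(rnorm(2000), nrow = 2), rate_hz = 100,
#'                      channels = tibble::tibble(label = c("A1", "A2")))
#' rec
#' @export
new_recording <- function(samples, rate_hz, channels = NULL, start_time_s = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples), rate_hz > 0)
  if (!all(is.finite(samples))) stop("recording contains non-finite samples", call. = FALSE)
  n_ch <- nrow(samples)
  if (is.null(channels)) {
    channels <- tibble::tibble(label = paste0("ch", seq_len(n_ch)))
  }
  channels <- tibble::as_tibble(channels)
  if (nrow(channels) != n_ch) stop("channel metadata rows must match signal rows", call. = FALSE)
  if (anyDuplicated(channels$label)) stop("channel labels must be unique", call. = FALSE)
  for (col in c("region", "hemisphere", "tissue", "kind")) {
    if (!col %in% names(channels)) channels[[col]] <- "unknown"
  }
  if (!"electrode" %in% names(channels)) {
    channels$electrode <- sub("[0-9]+$", "", channels$label)
  }
  structure(
    list(samples = samples, rate_hz = rate_hz, channels = channels,
         start_time_s = start_time_s),
    class = "sleeploop_recording"
  )
}

#' @export
print.sleeploop_recording <- function(x, ...) {
  cat(sprintf("<sleeploop_recording> %d channel(s) x %.1f s @ %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$rate_hz, x$rate_hz))
  print(x$channels, n = 8)
  invisible(x)
}

#' Recording duration in seconds
#' @param recording a [new_recording()] object.
#' @export
recording_duration <- function(recording) {
  ncol(recording$samples) / recording$rate_hz
}

#' Extract one channel's signal as a numeric vector
#'
#' @param recording a [new_recording()] object.
#' @param channel channel label or integer index.
#' @return numeric vector of samples (microvolts).
#' @export
channel_signal <- function(recording, channel) {
  i <- if (is.character(channel)) match(channel, recording$channels$label) else as.integer(channel)
  if (is.na(i) || i < 1L || i > nrow(recording$samples)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  recording$samples[i, ]
}

#' Sample times of a recording (seconds from recording start)
#' @param recording a [new_recording()] object.
#' @export
sample_times <- function(recording) {
  (seq_len(ncol(recording$samples)) - 1L) / recording$rate_hz
}

# time (s) -> 1-based sample index, clamped to the recording
time_to_index <- function(t_s, rate_hz, n) {
  pmin(pmax(1L, as.integer(floor(t_s * rate_hz)) + 1L), n)
}
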