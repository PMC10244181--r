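# Minimal European Data Format (EDF) I/O for continuous multichannel signals.
# EDF stores a 256-byte fixed-layout ASCII header, 256 bytes per signal of
# per-channel metadata, then little-endian int16 data records. Channel roles
# (region, tissue, macro/micro) do not fit EDF's header and travel in a
# sidecar CSV (see read_recording/write_recording).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file with a channel-metadata sidecar
#'
#' Signals are quantized to 16 bits over each channel's observed amplitude
#' range and written in 1-second data records; recordings are padded to a
#' whole number of seconds by repeating the final sample. Channel metadata
#' goes to `<path>.channels.csv` next to the EDF.
#'
#' @param recording a [new_recording()] object.
#' @param path output EDF path.
#' @param sidecar write the channel-metadata CSV (default TRUE).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, sidecar = TRUE) {
  rec <- recording
  rate <- rec$rate_hz
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  n <- ncol(rec$samples)
  n_ch <- nrow(rec$samples)
  n_rec <- ceiling(n / rate)
  pad_n <- n_rec * rate - n
  x <- if (pad_n > 0) cbind(rec$samples, rec$samples[, rep(n, pad_n), drop = FALSE]) else rec$samples

  phys_min <- apply(x, 1, min)
  phys_max <- apply(x, 1, max)
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32767; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("sleeploop synthetic", 80), edf_pad("sleeploop recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + n_ch), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(1), 8), edf_pad(n_ch, 4),
    paste(vapply(rec$channels$label, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), n_ch), collapse = ""),
    paste(rep(edf_pad("uV", 8), n_ch), collapse = ""),
    paste(vapply(phys_min, function(v) edf_pad(formatC(v, digits = 5, format = "g"), 8), ""), collapse = ""),
    paste(vapply(phys_max, function(v) edf_pad(formatC(v, digits = 5, format = "g"), 8), ""), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), n_ch), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), n_ch), collapse = ""),
    paste(rep(edf_pad("", 80), n_ch), collapse = ""),
    paste(rep(edf_pad(rate, 8), n_ch), collapse = ""),
    paste(rep(edf_pad("", 32), n_ch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (ch in seq_len(n_ch)) {
      dig <- round((x[ch, idx] - phys_min[ch]) * scale[ch] + dig_min)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  if (sidecar) {
    utils::write.csv(rec$channels, paste0(path, ".channels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an EDF recording (with optional channel-metadata sidecar)
#'
#' @param path EDF file path. If `<path>.channels.csv` exists its rows are
#'   attached as channel metadata; otherwise metadata defaults to
#'   `"unknown"` with a warning.
#' @return a [new_recording()] object.
#' @export
read_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  # EDF headers are ASCII; treat bytes as latin1 so corrupt files fail with
  # a format error instead of an encoding error
  rd <- function(nc) {
    r <- readBin(con, "raw", nc)
    trimws(iconv(rawToChar(r[r != as.raw(0)]), "latin1", "ASCII", sub = ""))
  }
  version <- rd(8)
  if (!identical(version, "0")) stop("not an EDF file (bad version field): ", path, call. = FALSE)
  rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(n_ch) || n_ch < 1L) stop("corrupt EDF header: ", path, call. = FALSE)
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  for (i in seq_len(n_ch)) rd(80)  # transducer
  for (i in seq_len(n_ch)) rd(8)   # physical dimension
  phys_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(n_ch)) rd(80)  # prefiltering
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(n_ch)) rd(32)
  if (length(unique(spr)) != 1L) stop("channels with different sampling rates are not supported", call. = FALSE)
  rate <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, endian = "little")
      out[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (dig - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }
  sidecar <- paste0(path, ".channels.csv")
  if (file.exists(sidecar)) {
    meta <- tibble::as_tibble(utils::read.csv(sidecar, stringsAsFactors = FALSE))
    missing <- setdiff(labels, meta$label)
    if (length(missing)) {
      warning("channels missing from sidecar, metadata set to unknown: ",
              paste(missing, collapse = ", "))
      meta <- dplyr::bind_rows(meta, tibble::tibble(label = missing))
    }
    meta <- meta[match(labels, meta$label), , drop = FALSE]
    meta[is.na(meta)] <- "unknown"
  } else {
    warning("no channel sidecar found; channel metadata set to unknown")
    meta <- tibble::tibble(label = labels)
  }
  new_recording(out, rate_hz = rate, channels = meta)
}
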