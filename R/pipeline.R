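# End-to-end pipeline plumbing: configuration, stage chaining, tidy CSV/JSON
# writers, and the run manifest.

#' Pipeline configuration
#'
#' Bundles the inputs and channel roles for [run_pipeline()]. Either a
#' synthetic generator configuration or an EDF path must be supplied.
#'
#' @param synth a [synthetic_config()] to simulate the recording, or NULL.
#' @param recording_path EDF path to load instead of simulating.
#' @param probe_channel MTL probe channel driving the closed-loop
#'   controller.
#' @param score_channel channel used for sleep scoring (defaults to the
#'   probe; in practice a spindle-rich neocortical contact distant from the
#'   seizure-onset zone, chosen by the analyst).
#' @param ripple_channel,ripple_reference gray-matter MTL contact and
#'   white-matter reference for bipolar ripple detection (NULL disables
#'   ripple analysis).
#' @param protocol a [stim_protocol()].
#' @param score_sleep run the Gaussian-mixture NREM scorer (default TRUE).
#'   With FALSE (e.g. curated all-NREM segments) every epoch is treated as
#'   NREM.
#' @param out_dir output directory for CSV/JSON artifacts (NULL = return
#'   results only).
#' @param seed integer master seed.
#' @return a named list of class `sleeploop_pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, recording_path = NULL,
                            probe_channel = "ch1", score_channel = probe_channel,
                            ripple_channel = NULL, ripple_reference = NULL,
                            protocol = stim_protocol(), score_sleep = TRUE,
                            out_dir = NULL, seed = 1L) {
  if (is.null(synth) && is.null(recording_path)) {
    stop("supply either a synthetic config or a recording path", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sleeploop_pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `synth` and
#' `protocol` sub-maps are passed to [synthetic_config()] and
#' [stim_protocol()].
#'
#' @param path YAML file.
#' @return a `sleeploop_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synthetic_config, y$synth)
  if (!is.null(y$protocol)) y$protocol <- do.call(stim_protocol, y$protocol)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Chains simulate (optional) -> line-noise removal -> IED detection and
#' validity masking -> sleep scoring -> closed-loop simulation and timing
#' audit -> event detection (slow waves, spindles, ripples) -> sham
#' construction and stimulation-response indices. When `out_dir` is set,
#' events, hypnogram, stimulation log and a JSON manifest (package version,
#' seed, parameters, every exclusion decision) are written there.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return list with `recording`, `truth` (if simulated), `channel_report`,
#'   `hypnogram`, `valid`, `stim_log`, `audit`, `events`, `sham`,
#'   `response`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "sleeploop_pipeline_config"))
  exclusions <- list()

  # --- input
  truth <- NULL
  if (!is.null(config$synth)) {
    sim <- generate_recording(config$synth)
    rec <- sim$recording; truth <- sim$truth
  } else {
    rec <- read_recording(config$recording_path)
  }
  labels <- rec$channels$label
  for (role in c("probe_channel", "score_channel")) {
    if (!config[[role]] %in% labels) {
      stop(sprintf("%s '%s' not present in the recording", role, config[[role]]),
           call. = FALSE)
    }
  }
  rate <- rec$rate_hz
  n <- ncol(rec$samples)

  # --- preprocess
  rec <- remove_line_noise(rec)
  ieds <- dplyr::bind_rows(lapply(labels, function(lb) {
    ev <- detect_ieds(channel_signal(rec, lb), rate)
    if (nrow(ev)) ev$channel <- lb
    ev
  }))
  vm <- build_validity_mask(rec, ieds)
  excluded_ch <- vm$channels$label[vm$channels$excluded]
  if (length(excluded_ch)) {
    exclusions$channels_high_ied_rate <- excluded_ch
  }

  # --- sleep scoring
  score_x <- channel_signal(rec, config$score_channel)
  powers <- band_power_series(score_x, rate, vm$mask[config$score_channel, ])
  if (isTRUE(config$score_sleep)) {
    hyp <- consolidate(score_nrem(powers, seed = config$seed))
  } else {
    hyp <- tibble::tibble(epoch = powers$epoch,
                          epoch_start_s = powers$epoch_start_s,
                          label = "NREM", posterior_nrem = 1)
  }
  nrem_mask <- rep(FALSE, n)
  for (i in seq_len(nrow(hyp))) {
    if (!is.na(hyp$label[i]) && hyp$label[i] == "NREM") {
      i0 <- time_to_index(hyp$epoch_start_s[i], rate, n)
      i1 <- time_to_index(hyp$epoch_start_s[i] + 30, rate, n) - 1L
      nrem_mask[i0:i1] <- TRUE
    }
  }

  # --- closed-loop simulation + audit on the probe channel
  probe_x <- channel_signal(rec, config$probe_channel)
  probe_valid <- vm$mask[config$probe_channel, ] & nrem_mask
  stim_log <- run_closed_loop(probe_x, rate, config$protocol, seed = config$seed)
  probe_cand <- detect_slow_waves(probe_x, rate, probe_valid,
                                  amplitude_criterion = FALSE)
  audit <- if (nrow(probe_cand) > 0 && nrow(stim_log$stims) > 0) {
    audit_stim_timing(stim_log, probe_cand$peak_s)
  } else NULL

  # --- event detection per channel
  events <- list(); qual_report <- list()
  for (lb in setdiff(labels, excluded_ch)) {
    x <- channel_signal(rec, lb)
    valid <- vm$mask[lb, ] & nrem_mask
    sw <- detect_slow_waves(x, rate, valid)
    if (nrow(sw)) { sw$channel <- lb; events[[length(events) + 1L]] <- sw }
    q <- qualify_spindle_channel(x, rate, valid)
    qual_report[[lb]] <- q
    if (isTRUE(q$qualified)) {
      sp <- detect_spindles(x, rate, valid)
      if (nrow(sp)) { sp$channel <- lb; events[[length(events) + 1L]] <- sp }
    } else {
      exclusions$spindle_unqualified <- c(exclusions$spindle_unqualified, lb)
    }
  }
  if (!is.null(config$ripple_channel)) {
    gx <- channel_signal(rec, config$ripple_channel)
    bip <- if (!is.null(config$ripple_reference)) {
      bipolar_reference(gx, channel_signal(rec, config$ripple_reference))
    } else gx
    valid <- vm$mask[config$ripple_channel, ] & nrem_mask
    rip <- detect_ripples(bip, rate, valid)
    if (!rip$qualified) {
      exclusions$ripple_unqualified <- config$ripple_channel  # ripple rate too low
    }
    if (nrow(rip$events)) {
      rip$events$channel <- config$ripple_channel
      events[[length(events) + 1L]] <- rip$events
    }
  }
  events <- dplyr::bind_rows(events)

  # --- stimulation response on the probe channel's spindles
  sham <- NULL; response <- NULL
  if (nrow(stim_log$stims) > 0) {
    pause_mask <- rep(FALSE, n)
    for (i in which(stim_log$blocks$kind == "PAUSE")) {
      i0 <- time_to_index(stim_log$blocks$start_s[i], rate, n)
      i1 <- time_to_index(stim_log$blocks$end_s[i], rate, n)
      pause_mask[i0:i1] <- TRUE
    }
    pause_peaks <- probe_cand$peak_s[pause_mask[time_to_index(probe_cand$peak_s, rate, n)]]
    if (length(pause_peaks)) {
      sham <- generate_sham_events(stim_log, pause_peaks, seed = config$seed)
      sp_probe <- events[events$kind == "spindle" &
                           events$channel == config$probe_channel, , drop = FALSE]
      if (nrow(sp_probe)) {
        p_stim <- event_probability(sp_probe$peak_s, stim_log$stims$time_s, 3)
        p_sham <- event_probability(sp_probe$peak_s, sham$time_s, 3)
        response <- list(
          immediate = immediate_contrast(p_stim$probability, p_sham$probability),
          prolonged = tryCatch(
            prolonged_enhancement(sp_probe$peak_s, stim_log$blocks),
            error = function(e) NULL))
      }
    }
  }

  manifest <- list(
    package = "sleeploop",
    version = as.character(utils::packageVersion("sleeploop")),
    seed = config$seed,
    rate_hz = rate, n_samples = n,
    probe_channel = config$probe_channel, score_channel = config$score_channel,
    protocol = unclass(config$protocol)[c("mode", "initial_threshold_uv",
                                          "initial_delay_ms", "delay_mode",
                                          "lockout_s", "block_s", "pause_s")],
    exclusions = exclusions)

  qual_tbl <- dplyr::bind_rows(qual_report, .id = "channel")

  out <- list(recording = rec, truth = truth,
              channel_report = vm$channels,
              spindle_qualification = qual_tbl, hypnogram = hyp,
              valid = vm$mask, stim_log = stim_log, audit = audit,
              events = events, sham = sham, response = response,
              manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(events, file.path(config$out_dir, "events.csv"), row.names = FALSE)
    utils::write.csv(hyp, file.path(config$out_dir, "hypnogram.csv"), row.names = FALSE)
    utils::write.csv(stim_log$stims, file.path(config$out_dir, "stimulations.csv"),
                     row.names = FALSE)
    utils::write.csv(vm$channels, file.path(config$out_dir, "channel_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Write an event tibble to CSV
#'
#' Fixed-column tidy interchange format: times in seconds from recording
#' start, half-open `[onset_s, offset_s)` intervals.
#'
#' @param events event tibble.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read an event tibble written by [write_events()]
#' @param path CSV path.
#' @return tibble.
#' @export
read_events <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
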