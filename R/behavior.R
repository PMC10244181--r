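# Overnight memory scoring for the visual paired-associate (vPAL) task,
# the binomial superiority test, bootstrap confidence estimates, vigilance
# change, and physiology-memory correlation.

#' Recognition accuracy of one vPAL test session
#'
#' `accuracy = N_correct_recognition / n_targets - N_false_recognition /
#' n_lures`: the hit rate among learned items minus the false-alarm rate
#' among lures. Bounded in [-1, 1].
#'
#' @param session trial tibble with columns `item_id`, `is_lure` (logical)
#'   and `response` (`"old"`/`"new"`); see
#'   [generate_behavioral_responses()].
#' @param n_targets,n_lures expected trial counts (defaults 25 and 15).
#' @return one-row tibble: `accuracy`, `n_correct`, `n_false`,
#'   `pairing_accuracy` (fraction of correct pairings among recognized
#'   targets, NA when none apply).
#' @export
recognition_accuracy <- function(session, n_targets = 25, n_lures = 15) {
  session <- tibble::as_tibble(session)
  nt <- sum(!session$is_lure); nl <- sum(session$is_lure)
  if (nt != n_targets || nl != n_lures) {
    stop(sprintf("incomplete session: expected %d targets and %d lures, got %d and %d",
                 n_targets, n_lures, nt, nl), call. = FALSE)
  }
  if (anyNA(session$response)) {
    stop("missing responses for item_id: ",
         paste(session$item_id[is.na(session$response)], collapse = ", "), call. = FALSE)
  }
  hits <- sum(!session$is_lure & session$response == "old")
  fa <- sum(session$is_lure & session$response == "old")
  pairing <- NA_real_
  if ("pairing_correct" %in% names(session)) {
    rec <- !session$is_lure & session$response == "old" & !is.na(session$pairing_correct)
    if (any(rec)) pairing <- mean(session$pairing_correct[rec])
  }
  tibble::tibble(accuracy = hits / n_targets - fa / n_lures,
                 n_correct = hits, n_false = fa, pairing_accuracy = pairing)
}

#' Intervention efficacy across the four vPAL sessions
#'
#' Overnight change on the stimulation night minus overnight change on the
#' undisturbed night:
#' `efficacy = (A_int_morning - A_int_evening) - (A_und_morning -
#' A_und_evening)`. Participants with recognition accuracy below
#' `exclusion_accuracy` in any single test are flagged for exclusion
#' (low attention / task misunderstanding).
#'
#' @param sessions tibble with columns `night`
#'   (`"intervention"`/`"undisturbed"`), `time` (`"evening"`/`"morning"`)
#'   and `accuracy` — one row per test (see [recognition_accuracy()]).
#' @param exclusion_accuracy exclusion threshold (default 0.1).
#' @return one-row tibble: `efficacy`, `delta_intervention`,
#'   `delta_undisturbed`, `excluded`.
#' @export
intervention_efficacy <- function(sessions, exclusion_accuracy = 0.1) {
  sessions <- tibble::as_tibble(sessions)
  need <- tidyr::expand_grid(night = c("intervention", "undisturbed"),
                             time = c("evening", "morning"))
  j <- dplyr::left_join(need, sessions, by = c("night", "time"))
  if (anyNA(j$accuracy)) {
    miss <- j[is.na(j$accuracy), c("night", "time")]
    stop("missing session(s): ",
         paste(miss$night, miss$time, collapse = "; "), call. = FALSE)
  }
  acc <- function(n, t) j$accuracy[j$night == n & j$time == t]
  d_int <- acc("intervention", "morning") - acc("intervention", "evening")
  d_und <- acc("undisturbed", "morning") - acc("undisturbed", "evening")
  tibble::tibble(efficacy = d_int - d_und,
                 delta_intervention = d_int, delta_undisturbed = d_und,
                 excluded = any(j$accuracy < exclusion_accuracy))
}

#' Binomial test of superior performance on stimulation nights
#'
#' Upper-tail binomial probability `P(X >= n_superior)` under the null that
#' each participant is equally likely to perform better on either night
#' (p = 0.5), plus the maximum-likelihood estimate and exact
#' (Clopper-Pearson) 95% confidence interval of the superiority
#' proportion.
#'
#' @param n_superior participants with superior stimulation-night
#'   performance.
#' @param n_participants total participants.
#' @return one-row tibble: `p_value`, `estimate`, `ci_lower`, `ci_upper`.
#' @examples
#' binomial_superiority(6, 6)$p_value  # (1/2)^6 = 0.015625
#' @export
binomial_superiority <- function(n_superior, n_participants) {
  stopifnot(n_superior >= 0, n_superior <= n_participants)
  p <- stats::pbinom(n_superior - 1, n_participants, 0.5, lower.tail = FALSE)
  bt <- stats::binom.test(n_superior, n_participants)
  tibble::tibble(p_value = p,
                 estimate = n_superior / n_participants,
                 ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2])
}

#' Bootstrap distribution of a session's recognition accuracy
#'
#' Resamples the session's target trials (n = 25) and lure trials (n = 15)
#' with replacement and rescores, `n_boot` times.
#'
#' @param session trial tibble as in [recognition_accuracy()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, and `distribution` (numeric vector of
#'   replicate accuracies).
#' @export
bootstrap_accuracy <- function(session, n_boot = 1000, seed = 1L) {
  session <- tibble::as_tibble(session)
  targ <- session[!session$is_lure, , drop = FALSE]
  lure <- session[session$is_lure, , drop = FALSE]
  nt <- nrow(targ); nl <- nrow(lure)
  set.seed(seed)
  dist <- vapply(seq_len(n_boot), function(i) {
    ht <- sum(targ$response[sample.int(nt, nt, replace = TRUE)] == "old")
    fa <- sum(lure$response[sample.int(nl, nl, replace = TRUE)] == "old")
    ht / nt - fa / nl
  }, 0)
  list(mean = mean(dist), sd = stats::sd(dist), distribution = dist)
}

#' Overnight change in psychomotor-vigilance reaction time
#'
#' Difference between the median morning and median evening reaction times
#' (seconds); negative values mean faster morning responses.
#'
#' @param evening_rt_s,morning_rt_s reaction-time vectors, seconds.
#' @param min_trials minimum valid trials per session (default 10).
#' @return median difference, seconds.
#' @export
pvt_change <- function(evening_rt_s, morning_rt_s, min_trials = 10) {
  evening_rt_s <- evening_rt_s[is.finite(evening_rt_s)]
  morning_rt_s <- morning_rt_s[is.finite(morning_rt_s)]
  if (length(evening_rt_s) < min_trials || length(morning_rt_s) < min_trials) {
    stop("need at least ", min_trials, " valid reaction times per session", call. = FALSE)
  }
  stats::median(morning_rt_s) - stats::median(evening_rt_s)
}

#' Correlation between a physiology index and intervention efficacy
#'
#' Spearman rank correlation (two-sided) across participants or electrode
#' pairs.
#'
#' @param physiology numeric vector (e.g. per-participant spindle
#'   enhancement scores).
#' @param efficacy numeric vector of matching intervention-efficacy values.
#' @return one-row tibble: `rho`, `p_value`, `n`.
#' @export
physiology_memory_correlation <- function(physiology, efficacy) {
  ok <- is.finite(physiology) & is.finite(efficacy)
  if (sum(ok) < 4) stop("need at least 4 paired values", call. = FALSE)
  if (stats::sd(physiology[ok]) == 0 || stats::sd(efficacy[ok]) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(stats::cor.test(physiology[ok], efficacy[ok],
                                         method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
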