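#' Signal-detection discriminability index
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with the standard extreme-rate
#' correction: rates of exactly 0 and 1 are clamped to `1/(2n)` and
#' `1 - 1/(2n)` before the inverse-normal transform (the z function is the
#' package's own [inverse_normal_cdf()]).
#'
#' @param hit_rate,fa_rate proportions in \[0, 1\].
#' @param n_trials number of trials behind each rate (>= 1), used by the
#'   clamping rule.
#' @return d-prime, dimensionless; vectorised over rates.
#' @export
d_prime <- function(hit_rate, fa_rate, n_trials) {
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1))
    stop("rates must lie in [0, 1]")
  if (any(n_trials < 1)) stop("n_trials must be >= 1")
  clamp <- function(r) pmin(pmax(r, 1 / (2 * n_trials)), 1 - 1 / (2 * n_trials))
  inverse_normal_cdf(clamp(hit_rate)) - inverse_normal_cdf(clamp(fa_rate))
}

#' Summarise a vigilance session
#'
#' Counts trial outcomes and computes rates and d-prime. Following
#' signal-detection convention for this task, false alarms are premature
#' responses during the intertrial interval (`fa_rate = premature /
#' n_trials`); incorrect-port responses are tallied separately. Set
#' `fa_includes_incorrect = TRUE` to fold incorrect responses into the
#' false-alarm rate.
#'
#' @param events event-log data.frame (`t_s`, `event`, `port`), e.g. from
#'   [simulate_session()] or [parse_event_log()].
#' @param fa_includes_incorrect include incorrect-port responses in the
#'   false-alarm rate.
#' @return object of class `session_summary`: `n_trials`, `hits`, `misses`,
#'   `incorrect`, `premature`, `hit_rate`, `fa_rate`, `d_prime`.
#' @export
summarize_session <- function(events, fa_includes_incorrect = FALSE) {
  n_trials <- sum(events$event == "trial_start")
  if (n_trials == 0) stop("zero trials in event log")
  hits <- sum(events$event == "hit")
  misses <- sum(events$event == "miss")
  incorrect <- sum(events$event == "incorrect")
  premature <- sum(events$event == "premature")
  if (hits + misses + incorrect + premature != n_trials)
    stop("corrupted log: outcomes do not sum to the number of trials")
  hit_rate <- hits / n_trials
  fa <- premature + if (fa_includes_incorrect) incorrect else 0
  fa_rate <- fa / n_trials
  structure(list(n_trials = n_trials, hits = hits, misses = misses,
                 incorrect = incorrect, premature = premature,
                 hit_rate = hit_rate, fa_rate = fa_rate,
                 d_prime = d_prime(hit_rate, fa_rate, n_trials)),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %d trials: %d hit / %d miss / %d incorrect / %d premature; hit rate %.3f, FA rate %.3f, d' = %.3f\n",
              x$n_trials, x$hits, x$misses, x$incorrect, x$premature,
              x$hit_rate, x$fa_rate, x$d_prime))
  invisible(x)
}

#' Baseline performance from the last three training sessions
#'
#' Baseline is the mean hit rate and mean d-prime over exactly three pre-drug
#' sessions; performance is stable when every session's hit rate lies within
#' `tol` (default 30%) of the three-session mean.
#'
#' @param sessions list of exactly 3 `session_summary` objects.
#' @param tol relative stability tolerance on hit rate.
#' @return list: `hit_rate`, `d_prime` (means), `stable` (logical).
#' @export
baseline_performance <- function(sessions, tol = 0.30) {
  if (length(sessions) != 3) stop("exactly 3 baseline sessions required")
  hr <- vapply(sessions, function(s) s$hit_rate, numeric(1))
  dp <- vapply(sessions, function(s) s$d_prime, numeric(1))
  m <- mean(hr)
  if (m <= 0) stop("zero baseline hit rate")
  list(hit_rate = m, d_prime = mean(dp),
       stable = max(abs(hr - m)) / m < tol)
}

#' Percent change of a session from baseline
#'
#' `100 * (value - baseline) / |baseline|` for hit rate and d-prime. Sessions
#' whose baseline d-prime is below `dprime_floor` in magnitude are flagged
#' (`dprime_reliable = FALSE`) because small denominators make the percent
#' change unstable.
#'
#' @param session a `session_summary`.
#' @param baseline a [baseline_performance()] result.
#' @param dprime_floor magnitude below which the d-prime percent change is
#'   flagged unreliable (default 0.1).
#' @return list: `pct_change_hit_rate`, `pct_change_dprime`,
#'   `dprime_reliable`.
#' @export
percent_change <- function(session, baseline, dprime_floor = 0.1) {
  if (baseline$hit_rate <= 0) stop("zero baseline hit rate")
  list(
    pct_change_hit_rate = 100 * (session$hit_rate - baseline$hit_rate) /
      abs(baseline$hit_rate),
    pct_change_dprime = 100 * (session$d_prime - baseline$d_prime) /
      abs(baseline$d_prime),
    dprime_reliable = abs(baseline$d_prime) >= dprime_floor)
}

#' Assemble a dose-response function
#'
#' Per-dose percent-change-from-baseline measures averaged over drug-testing
#' cycles (the full ladder is typically run twice and the two determinations
#' averaged). Doses are emitted in ascending order with saline (dose 0)
#' first.
#'
#' @param sessions data.frame with one row per (dose, cycle) determination:
#'   columns `dose` (mg/kg; 0 = saline), `cycle`, and the session's
#'   `session_summary` stored in list-column `summary` — or, more simply,
#'   pre-computed `pct_change_hit_rate` / `pct_change_dprime` columns.
#' @param baselines named list: cycle -> [baseline_performance()] result;
#'   required when `sessions` carries raw summaries.
#' @return data.frame: `dose`, `pct_change_hit_rate`, `pct_change_dprime`,
#'   `n_determinations`.
#' @export
dose_response <- function(sessions, baselines = NULL) {
  if (!"dose" %in% names(sessions)) stop("sessions must have a dose column")
  if (!"pct_change_hit_rate" %in% names(sessions)) {
    if (is.null(baselines)) stop("baselines required for raw session input")
    pc <- lapply(seq_len(nrow(sessions)), function(i) {
      percent_change(sessions$summary[[i]],
                     baselines[[as.character(sessions$cycle[i])]])
    })
    sessions$pct_change_hit_rate <- vapply(pc, `[[`, numeric(1),
                                           "pct_change_hit_rate")
    sessions$pct_change_dprime <- vapply(pc, `[[`, numeric(1),
                                         "pct_change_dprime")
  }
  doses <- sort(unique(sessions$dose))
  rows <- lapply(doses, function(d) {
    sub <- sessions[sessions$dose == d, , drop = FALSE]
    if (nrow(sub) == 0) stop("dose with no sessions: ", d)
    data.frame(dose = d,
               pct_change_hit_rate = mean(sub$pct_change_hit_rate),
               pct_change_dprime = mean(sub$pct_change_dprime),
               n_determinations = nrow(sub))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
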