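#' Vigilance-task simulation parameters
#'
#' Trial-by-trial generative model of a psychomotor vigilance session: a trial
#' starts with house-light illumination, a variable intertrial interval (ITI)
#' is drawn uniformly from `iti_set`, then one of two nose-poke ports is lit
#' with equal probability. A premature poke during the ITI ends the trial
#' (false alarm) and triggers a timeout. Given the cue, the animal responds
#' with probability `hit_prob / (1 - incorrect_prob)`; a response lands on the
#' dark port with probability `incorrect_prob`, so hits occur with probability
#' `hit_prob` and the remainder are misses.
#'
#' @param hit_prob probability of a correct response within the window.
#' @param premature_rate hazard of a premature poke per second of ITI.
#' @param incorrect_prob probability that a response hits the dark port.
#' @param session_length session duration, s (default 3600 = 60 min).
#' @param iti_set allowed intertrial intervals, s (default 15/30/45).
#' @param response_window response deadline after cue onset, s (default 5).
#' @param timeout post-outcome delay before the next trial, s (default 10).
#' @param seed integer RNG seed.
#' @return object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(hit_prob = 0.7, premature_rate = 0.005,
                                incorrect_prob = 0.05, session_length = 3600,
                                iti_set = c(15, 30, 45), response_window = 5,
                                timeout = 10, seed = 1L) {
  if (hit_prob < 0 || hit_prob > 1) stop("hit_prob must lie in [0, 1]")
  if (incorrect_prob < 0 || incorrect_prob >= 1)
    stop("incorrect_prob must lie in [0, 1)")
  if (hit_prob / (1 - incorrect_prob) > 1 + 1e-12)
    stop("hit_prob / (1 - incorrect_prob) exceeds 1: inconsistent response model")
  if (premature_rate < 0) stop("premature_rate must be >= 0")
  if (any(iti_set <= 0) || session_length <= 0 || response_window <= 0)
    stop("durations must be positive")
  structure(list(hit_prob = hit_prob, premature_rate = premature_rate,
                 incorrect_prob = incorrect_prob,
                 session_length = session_length, iti_set = iti_set,
                 response_window = response_window, timeout = timeout,
                 seed = as.integer(seed)),
            class = "behavior_sim_params")
}

#' Simulate one vigilance session
#'
#' Trials are generated until `session_length` is exhausted (a trial whose ITI
#' would start past the session end is not begun). Events are stamped with
#' second-resolution times; every `cue_on` is followed by exactly one of
#' `hit`, `miss`, `incorrect` before the next `trial_start`.
#'
#' @param params a [behavior_sim_params()].
#' @return data.frame event log with columns `t_s`, `event`, `port`;
#'   deterministic given `params$seed`.
#' @export
simulate_session <- function(params) {
  stopifnot(inherits(params, "behavior_sim_params"))
  with_seed(params$seed, {
    rows <- list()
    add <- function(t, event, port = "none")
      rows[[length(rows) + 1]] <<- data.frame(t_s = round(t, 3), event = event,
                                              port = port)
    t <- 0
    p_resp <- if (params$incorrect_prob > 0)
      min(1, params$hit_prob / (1 - params$incorrect_prob)) else params$hit_prob
    while (t < params$session_length) {
      iti <- sample(params$iti_set, 1)
      if (t + iti >= params$session_length) break
      add(t, "trial_start")
      # premature poke: exponential waiting time against the ITI
      prem_t <- if (params$premature_rate > 0)
        stats::rexp(1, params$premature_rate) else Inf
      if (prem_t < iti) {
        add(t + prem_t, "premature",
            port = sample(c("left", "right"), 1))
        add(t + prem_t, "timeout")
        t <- t + prem_t + params$timeout
        next
      }
      port <- sample(c("left", "right"), 1)
      cue_t <- t + iti
      add(cue_t, "cue_on", port)
      if (stats::runif(1) < p_resp) {
        rt <- stats::runif(1, 0.2, params$response_window)
        if (stats::runif(1) < params$incorrect_prob) {
          other <- setdiff(c("left", "right"), port)
          add(cue_t + rt, "incorrect", other)
          add(cue_t + rt, "timeout")
          t <- cue_t + rt + params$timeout
        } else {
          add(cue_t + rt, "hit", port)
          add(cue_t + rt, "reward")
          t <- cue_t + rt + params$timeout
        }
      } else {
        add(cue_t + params$response_window, "miss")
        t <- cue_t + params$response_window
      }
    }
    if (length(rows) == 0)
      return(data.frame(t_s = numeric(), event = character(),
                        port = character()))
    do.call(rbind, rows)
  })
}

#' Write / read a vigilance event log as TSV
#'
#' Dialect: tab-separated columns `t_s`, `event`, `port`; header row
#' mandatory.
#'
#' @param events event-log data.frame.
#' @param path file path.
#' @return `path`, invisibly; `parse_event_log` returns a validated event
#'   data.frame.
#' @export
write_event_log <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
parse_event_log <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty event log")
    return(data.frame(t_s = numeric(), event = character(),
                      port = character()))
  }
  need <- c("t_s", "event", "port")
  if (!all(need %in% names(df)))
    stop("event log must have columns t_s, event, port")
  vocab <- c("trial_start", "cue_on", "hit", "miss", "incorrect", "premature",
             "reward", "timeout")
  bad <- which(!df$event %in% vocab)
  if (length(bad))
    stop("unknown event token(s) '", paste(unique(df$event[bad]), collapse = "', '"),
         "' at line(s) ", paste(bad + 1, collapse = ", "))
  if (any(diff(df$t_s) < 0))
    stop("non-monotone timestamps at line(s) ",
         paste(which(diff(df$t_s) < 0) + 2, collapse = ", "))
  df[need]
}
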