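# build a minimal consistent event log from outcome counts
toy_log <- function(hits = 0, misses = 0, incorrect = 0, premature = 0) {
  rows <- list(); t <- 0
  add <- function(ev, port = "none") {
    rows[[length(rows) + 1]] <<- data.frame(t_s = t, event = ev, port = port)
    t <<- t + 1
  }
  emit <- function(outcome) {
    add("trial_start")
    if (outcome == "premature") { add("premature", "left"); add("timeout") }
    else {
      add("cue_on", "left")
      add(outcome, if (outcome == "incorrect") "right" else "left")
      if (outcome == "hit") add("reward")
    }
  }
  for (i in seq_len(hits)) emit("hit")
  for (i in seq_len(misses)) emit("miss")
  for (i in seq_len(incorrect)) emit("incorrect")
  for (i in seq_len(premature)) emit("premature")
  do.call(rbind, rows)
}

test_that("d-prime matches the inverse-normal oracle and clamping rule", {
  expect_equal(d_prime(0.5, 0.5, 100), 0)
  expect_equal(d_prime(0.84, 0.16, 1e6), 1.98898, tolerance = 1e-4)
  # clamping: hit rate 1 with n = 40 evaluated at 39.5/40
  expect_equal(d_prime(1, 0.5, 40), qnorm(0.9875), tolerance = 1e-9)
  expect_equal(d_prime(0.5, 0, 40), -qnorm(1 / 80), tolerance = 1e-9)
  expect_error(d_prime(1.2, 0.5, 10), "rates")
})

test_that("d-prime properties: oracle grid, antisymmetry, monotonicity", {
  rates <- seq(0.01, 0.99, by = 0.01)
  grid <- expand.grid(h = rates, f = rates)
  got <- d_prime(grid$h, grid$f, 1e9)
  want <- qnorm(grid$h) - qnorm(grid$f)
  expect_lt(max(abs(got - want)), 1e-6)
  # antisymmetry
  expect_lt(max(abs(d_prime(grid$h, grid$f, 1e9) +
                    d_prime(grid$f, grid$h, 1e9))), 1e-9)
  # strictly increasing in hit rate at fixed fa, decreasing in fa at fixed hit
  expect_true(all(diff(d_prime(rates, 0.3, 1e9)) > 0))
  expect_true(all(diff(d_prime(0.7, rates, 1e9)) < 0))
})

test_that("session summaries count outcomes and rates correctly", {
  s <- summarize_session(toy_log(hits = 30, misses = 5, premature = 5))
  expect_equal(s$n_trials, 40)
  expect_equal(s$hit_rate, 0.75)
  expect_equal(s$fa_rate, 0.125)
  expect_equal(s$d_prime, d_prime(0.75, 0.125, 40))
  all_hits <- summarize_session(toy_log(hits = 10))
  expect_equal(all_hits$hit_rate, 1)
  expect_equal(all_hits$fa_rate, 0)
  # incorrect responses are tallied but excluded from fa_rate by default
  s2 <- summarize_session(toy_log(hits = 8, incorrect = 2))
  expect_equal(s2$fa_rate, 0)
  expect_equal(summarize_session(toy_log(hits = 8, incorrect = 2),
                                 fa_includes_incorrect = TRUE)$fa_rate, 0.2)
  corrupt <- toy_log(hits = 3)[-3, ]  # drop a hit event
  expect_error(summarize_session(corrupt), "corrupted")
  expect_error(summarize_session(toy_log()), "zero trials")
})

test_that("baseline stability uses the 30%-of-mean rule on hit rate", {
  mk <- function(hr) {
    n <- 20
    summarize_session(toy_log(hits = round(hr * n),
                              misses = n - round(hr * n)))
  }
  b <- baseline_performance(list(mk(0.6), mk(0.6), mk(0.6)))
  expect_equal(b$hit_rate, 0.6)
  expect_true(b$stable)
  expect_false(baseline_performance(list(mk(0.4), mk(0.6), mk(0.8)))$stable)
  expect_true(baseline_performance(list(mk(0.55), mk(0.6), mk(0.65)))$stable)
  expect_error(baseline_performance(list(mk(0.6), mk(0.6))), "exactly 3")
})

test_that("percent change is relative to the absolute baseline", {
  mk <- function(hits, misses) summarize_session(toy_log(hits, misses))
  b <- baseline_performance(list(mk(12, 8), mk(12, 8), mk(12, 8)))  # hr 0.6
  same <- percent_change(mk(12, 8), b)
  expect_equal(same$pct_change_hit_rate, 0)
  expect_equal(same$pct_change_dprime, 0)
  up <- percent_change(mk(18, 2), b)  # 0.9 vs 0.6
  expect_equal(up$pct_change_hit_rate, 50)
  s <- mk(12, 8); s$d_prime <- 1
  expect_equal(percent_change(s, list(hit_rate = 0.6, d_prime = 2))$pct_change_dprime,
               -50)
})

test_that("dose-response averages determinations with saline first", {
  df <- data.frame(dose = c(1, 1, 0, 0),
                   pct_change_hit_rate = c(10, 30, 0, 2),
                   pct_change_dprime = c(5, 15, 1, -1))
  dr <- dose_response(df)
  expect_equal(dr$dose, c(0, 1))
  expect_equal(dr$pct_change_hit_rate, c(1, 20))
  expect_equal(dr$n_determinations, c(2L, 2L))
  single <- dose_response(data.frame(dose = 3, pct_change_hit_rate = 7,
                                     pct_change_dprime = 2))
  expect_equal(single$n_determinations, 1L)
  # full ladder: saline + 5 doses in, 6 points out
  ladder <- data.frame(dose = rep(c(0, 0.01, 0.03, 0.3, 1, 3), each = 2),
                       pct_change_hit_rate = 0, pct_change_dprime = 0)
  expect_equal(nrow(dose_response(ladder)), 6)
})

test_that("event logs round trip and parsing validates tokens and order", {
  ev <- toy_log(hits = 3)
  path <- file.path(tempdir(), "session_roundtrip.tsv")
  write_event_log(ev, path)
  back <- parse_event_log(path)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(sum(back$event == "trial_start"), 3)
  bad <- ev; bad$event[2] <- "poke"
  write_event_log(bad, path)
  expect_error(parse_event_log(path), "poke")
  nonmono <- ev; nonmono$t_s[4] <- 0
  write_event_log(nonmono, path)
  expect_error(parse_event_log(path), "non-monotone")
  writeLines("t_s\tevent\tport", path)
  expect_warning(empty <- parse_event_log(path), "empty")
  expect_equal(nrow(empty), 0)
  unlink(path)
})

test_that("simulated sessions honour the outcome probabilities", {
  perfect <- summarize_session(simulate_session(
    behavior_sim_params(hit_prob = 1, premature_rate = 0, incorrect_prob = 0,
                        seed = 1)))
  expect_equal(perfect$hit_rate, 1)
  expect_equal(perfect$fa_rate, 0)
  # empirical hit rate near 0.5 over many trials (pooled binomial check)
  sums <- lapply(1:6, function(s) summarize_session(simulate_session(
    behavior_sim_params(hit_prob = 0.5, premature_rate = 0,
                        incorrect_prob = 0, iti_set = c(2, 3),
                        timeout = 1, seed = s))))
  hits <- sum(vapply(sums, `[[`, numeric(1), "hits"))
  n <- sum(vapply(sums, `[[`, numeric(1), "n_trials"))
  expect_gt(n, 500)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.5) / n
  expect_gt(hits / n, ci[1])
  expect_lt(hits / n, ci[2])
  # high premature hazard with weak detection drives d-prime negative
  noisy <- summarize_session(simulate_session(
    behavior_sim_params(hit_prob = 0.1, premature_rate = 0.2,
                        incorrect_prob = 0, seed = 2)))
  expect_gt(noisy$fa_rate, noisy$hit_rate)
  expect_lt(noisy$d_prime, 0)
  # determinism
  p <- behavior_sim_params(seed = 8)
  expect_identical(simulate_session(p), simulate_session(p))
})

test_that("session logs satisfy the trial-structure invariant", {
  ev <- simulate_session(behavior_sim_params(seed = 12))
  expect_true(all(diff(ev$t_s) >= 0))
  cue_idx <- which(ev$event == "cue_on")
  for (i in cue_idx) {
    nxt <- ev$event[(i + 1):nrow(ev)]
    outcome <- nxt[nxt %in% c("hit", "miss", "incorrect")][1]
    expect_false(is.na(outcome))
  }
  expect_equal(sum(ev$event %in% c("hit", "miss", "incorrect", "premature")),
               sum(ev$event == "trial_start"))
})

test_that("higher hit probability yields larger percent-change hit rate", {
  # sign property across seeded sessions: female-like preset (higher hit
  # probability under drug) beats the male-like preset on average
  pc <- function(hit_prob, seeds) {
    vapply(seeds, function(s) {
      base <- lapply(1:3, function(i) summarize_session(simulate_session(
        behavior_sim_params(hit_prob = 0.6, seed = 1000 * s + i))))
      bl <- baseline_performance(base)
      drug <- summarize_session(simulate_session(
        behavior_sim_params(hit_prob = hit_prob, seed = 7000 + s)))
      percent_change(drug, bl)$pct_change_hit_rate
    }, numeric(1))
  }
  seeds <- 1:25
  expect_gt(mean(pc(0.85, seeds)), mean(pc(0.65, seeds)))
})
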