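test_that("silent and always-licking agents give the hand-counted outcomes", {
  cfg <- default_config("DNMS")
  silent <- run_task_session(cfg, silent_agent(), seed = 1, n_trials = 24)
  expect_equal(sum(silent$trials$outcome == "Miss"), 12L)
  expect_equal(sum(silent$trials$outcome == "CorrectRejection"), 12L)
  expect_equal(silent$totals$reward_uL, 0)
  expect_equal(block_stats(silent$trials$outcome)$performance, 0.5)

  licker <- run_task_session(cfg, continuous_licker(), seed = 1,
                             n_trials = 24)
  expect_equal(sum(licker$trials$outcome == "Hit"), 12L)
  expect_equal(sum(licker$trials$outcome == "FalseChoice"), 12L)
  expect_equal(licker$totals$reward_uL, 12 * 5)  # 12 hits x 5 uL
})

test_that("a zero-trial session yields an empty result and a bare log", {
  cfg <- default_config("DNMS")
  rec <- run_task_session(cfg, silent_agent(), seed = 1, n_trials = 0)
  expect_equal(nrow(rec$trials), 0L)
  expect_equal(rec$events$kind, "session_end")
  expect_equal(rec$totals$reward_uL, 0)
})

test_that("event timing obeys the configured protocol structure", {
  for (p in c("DNMS", "DPA", "GNG")) {
    cfg <- default_config(p)
    rec <- run_task_session(cfg, bernoulli_agent(), seed = 3, n_trials = 24)
    tm <- log_timing(rec$events)
    # every odor pulse lasts exactly odor_duration
    expect_true(all(tm$pulses == 1000 * cfg$odor_duration_s))
    # fixed inter-trial interval between consecutive trials
    expect_true(all(tm$itis == 1000 * cfg$iti_s))
    if (!is.null(cfg$delay_range_s)) {
      # sample-offset to test-onset gap lies within the delay range
      ev <- rec$events[rec$events$kind %in% c("odor_on", "odor_off"), ]
      per_trial <- split(ev, ev$trial)
      delays <- vapply(per_trial, function(e) {
        e$t_ms[e$kind == "odor_on"][2] - e$t_ms[e$kind == "odor_off"][1]
      }, numeric(1))
      expect_true(all(delays >= 1000 * cfg$delay_range_s[1] &
                        delays <= 1000 * cfg$delay_range_s[2]))
    }
  }
})

test_that("reward delivery is instantaneous at the triggering lick", {
  cfg <- default_config("GNG")
  rec <- run_task_session(cfg, continuous_licker(), seed = 2, n_trials = 24)
  ev <- rec$events
  pump_t <- ev$t_ms[ev$kind == "pump_on"]
  lick_t <- ev$t_ms[ev$kind == "lick_on"]
  expect_true(all(pump_t %in% lick_t))
})

test_that("identical (config, agent, seed) triples reproduce the session", {
  cfg <- default_config("DPA")
  a <- run_task_session(cfg, delta_rule_learner(0.2, 0.5), seed = 9,
                        n_trials = 48)
  b <- run_task_session(cfg, delta_rule_learner(0.2, 0.5), seed = 9,
                        n_trials = 48)
  expect_identical(a, b)
  c <- run_task_session(cfg, delta_rule_learner(0.2, 0.5), seed = 10,
                        n_trials = 48)
  expect_false(identical(a$trials$outcome, c$trials$outcome))
})

test_that("an agent raising mid-session aborts with a flagged partial log", {
  cfg <- default_config("DNMS")
  n_seen <- 0L
  flaky <- odortask:::new_lick_agent("flaky", decide = function(ctx) {
    n_seen <<- n_seen + 1L
    if (n_seen > 5L) stop("sensor failure")
    numeric(0)
  })
  rec <- run_task_session(cfg, flaky, seed = 1, n_trials = 24)
  expect_true(rec$partial)
  expect_match(rec$termination_reason, "agent_error")
  expect_equal(nrow(rec$trials), 5L)
  # the partial log still validates cleanly
  expect_equal(nrow(validate_event_log(rec$events)), 0L)
})
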