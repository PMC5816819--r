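mk_events <- function(t, kind, odor = NA_character_) {
  n <- length(t)
  data.frame(t_ms = as.integer(t), kind = kind,
             odor = rep(odor, length.out = n),
             trial = rep(NA_integer_, n), volume_uL = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

test_that("log validation reports ordering, pairing and valve violations", {
  # empty log is clean
  expect_identical(nrow(validate_event_log(empty_df <- mk_events(
    integer(0), character(0)))), 0L)

  v <- validate_event_log(mk_events(c(100, 50), c("lick_on", "lick_off")))
  expect_true("non-monotone timestamp" %in% v$rule)

  v <- validate_event_log(mk_events(c(0, 50), c("lick_on", "lick_on")))
  expect_true("unterminated lick" %in% v$rule)
  expect_equal(v$index[v$rule == "unterminated lick"][1], 1L)

  v <- validate_event_log(mk_events(-5, "session_end"))
  expect_true("negative timestamp" %in% v$rule)

  v <- validate_event_log(mk_events(c(0, 10), c("odor_on", "odor_on"),
                                    odor = "Octane"))
  expect_true(any(v$rule %in% c("odor valve double-open",
                                "odor valve left open")))

  v <- validate_event_log(mk_events(0, "warp_drive"))
  expect_true("unknown event kind" %in% v$rule)

  clean <- mk_events(c(0, 30, 100, 130), rep(c("lick_on", "lick_off"), 2))
  expect_equal(nrow(validate_event_log(clean)), 0L)
})

test_that("every engine-produced log passes validation", {
  cfg <- default_config("DNMS")
  recs <- list(
    run_task_session(cfg, continuous_licker(), seed = 1, n_trials = 24),
    run_task_session(cfg, bernoulli_agent(), seed = 2, n_trials = 24),
    run_shaping_session(cfg, continuous_licker(), seed = 3),
    run_lick_teaching_session(cfg, continuous_licker(), seed = 4),
    run_lick_teaching_session(cfg, silent_agent(), seed = 5)
  )
  for (r in recs) {
    expect_equal(nrow(validate_event_log(r$events)), 0L,
                 info = paste("phase:", r$phase))
  }
})

test_that("session totals are conserved and recomputable from the log", {
  cfg <- default_config("DNMS")
  for (ag in list(continuous_licker(), bernoulli_agent(c(go = .7, nogo = .3)))) {
    rec <- run_task_session(cfg, ag, seed = 11, n_trials = 48)
    # per-trial rewards sum to the session total, which equals the volume
    # carried by pump events
    expect_equal(sum(rec$trials$reward_uL), rec$totals$reward_uL)
    pump_vol <- sum(rec$events$volume_uL[rec$events$kind == "pump_on"])
    expect_equal(pump_vol, rec$totals$reward_uL)
    # one result row per trial_start event
    expect_equal(nrow(rec$trials),
                 sum(rec$events$kind == "trial_start"))
    expect_equal(rec$totals$n_hits, sum(rec$trials$outcome == "Hit"))
  }
  te <- run_lick_teaching_session(cfg, continuous_licker(), seed = 6)
  expect_equal(sum(te$events$volume_uL[te$events$kind == "pump_on"]),
               te$totals$reward_uL)
  expect_equal(sum(te$bouts$volume_uL), te$totals$reward_uL)
  # drop deliveries beyond each bout opener: pump count x drop volume
  drops <- sum(te$events$kind == "pump_on") - te$totals$n_bouts
  expect_equal(drops * te$config$drop_uL,
               te$totals$reward_uL -
                 te$totals$n_bouts * te$config$initial_bout_uL)
})
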