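test_that("constructor preconditions are enforced", {
  expect_error(continuous_licker(0), "positive")
  expect_error(continuous_licker(-2), "positive")
  expect_error(bernoulli_agent(c(go = 1.2, nogo = 0)), "\\[0, 1\\]")
  expect_error(bernoulli_agent(c(yes = 1)), "named")
  expect_error(delta_rule_learner(alpha = 0), "alpha")
  expect_error(delta_rule_learner(alpha = 1.5), "alpha")
  expect_error(delta_rule_learner(p0 = 1), "p0")
  expect_error(make_agent("gerbil"), "unknown agent")
})

test_that("a continuous licker lands the expected licks in the window", {
  # 8 Hz over a 1.0 s window: licks at multiples of 125 ms; count them
  ag <- continuous_licker(8)
  ctx <- list(phase = "task", window = c(6.5, 7.5), slot_s = 18,
              t_start_s = 0)
  licks <- ag$decide(ctx)
  in_win <- licks[licks >= 6.5 & licks < 7.5]
  expect_equal(length(in_win), 8L)
  expect_true(all(abs(licks * 8 - round(licks * 8)) < 1e-9))
  # every go trial becomes a hit whenever the window exceeds one period
  rec <- run_task_session(default_config("GNG"), ag, seed = 1,
                          n_trials = 24)
  expect_equal(sum(rec$trials$outcome == "Hit"),
               sum(rec$trials$trial_type == "go"))
})

test_that("bernoulli extremes reproduce the perfect and silent agents", {
  cfg <- default_config("DNMS")
  perfect <- run_task_session(cfg, bernoulli_agent(c(go = 1, nogo = 0)),
                              seed = 1, n_trials = 48)
  expect_true(all(perfect$trials$outcome %in%
                    c("Hit", "CorrectRejection")))
  expect_equal(block_stats(perfect$trials$outcome)$performance, c(1, 1))

  never <- run_task_session(cfg, bernoulli_agent(c(go = 0, nogo = 0)),
                            seed = 1, n_trials = 24)
  silent <- run_task_session(cfg, silent_agent(), seed = 1, n_trials = 24)
  expect_identical(never$trials$outcome, silent$trials$outcome)
})

test_that("a fair-coin bernoulli agent performs at chance", {
  cfg <- default_config("GNG")
  # 2400 trials; binomial SE of the mean performance is 0.5/sqrt(2400)
  outs <- unlist(lapply(1:4, function(s) {
    run_task_session(cfg, bernoulli_agent(c(go = .5, nogo = .5)),
                     seed = s, n_trials = 600)$trials$outcome
  }))
  perf <- mean(outs %in% c("Hit", "CorrectRejection"))
  se <- 0.5 / sqrt(length(outs))
  expect_lt(abs(perf - 0.5), 3 * se)
})

test_that("the delta rule updates value only on licked trials", {
  ag <- delta_rule_learner(alpha = 1, p0 = 0.99)
  ag$reset(1)
  ctx <- list(phase = "task", paradigm = "DNMS", index = 1,
              seq_key = "A > B", trial_type = "go", window = c(6.5, 7.5),
              slot_s = 18, t_start_s = 0, mode = NA)
  set.seed(42)  # p0 = 0.99: licking is near-certain; draw until it licks
  licks <- ag$decide(ctx)
  expect_length(licks, 1L)
  ag$update("Hit", TRUE)
  expect_equal(unname(ag$values()["A > B"]), 1)  # one alpha=1 update

  # an unrewarded lick drives the value to zero under alpha = 1
  ag2 <- delta_rule_learner(alpha = 1, p0 = 0.99)
  ag2$reset(1)
  set.seed(42)
  ctx$trial_type <- "nogo"
  expect_length(ag2$decide(ctx), 1L)
  ag2$update("FalseChoice", FALSE)
  expect_equal(unname(ag2$values()["A > B"]), 0)

  # without a lick the value must not move
  ag3 <- delta_rule_learner(alpha = 0.5, p0 = 1e-9)
  ag3$reset(1)
  set.seed(7)  # p0 = 1e-9: the agent never licks
  for (i in 1:20) {
    expect_length(ag3$decide(ctx), 0L)
    ag3$update("Miss", FALSE)
  }
  expect_equal(unname(ag3$values()["A > B"]), 1e-9)
})

test_that("delta-rule hit rate climbs to ceiling and stays there", {
  cfg <- default_config("DNMS")
  cfg$max_session_s <- 1e6
  rec <- run_task_session(cfg, delta_rule_learner(0.1, 0.6), seed = 1,
                          n_trials = 480)
  bs <- block_stats(rec$trials$outcome)
  expect_gt(mean(tail(bs$hit_rate, 5)), 0.95)
  expect_gt(tail(bs$performance, 1), head(bs$performance, 1))
})
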