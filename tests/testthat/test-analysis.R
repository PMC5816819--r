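test_that("extreme rates are clipped to 1/(2n) and 1 - 1/(2n)", {
  expect_equal(clipped_rate(12, 12), 23 / 24)
  expect_equal(clipped_rate(0, 12), 1 / 24)
  expect_equal(clipped_rate(6, 12), 0.5)
  expect_equal(clipped_rate(1, 1), 0.5)
  expect_error(clipped_rate(1, 0), "n must be at least 1")
  expect_error(clipped_rate(13, 12), "0 <= k <= n")
})

test_that("d-prime matches frozen quantile values and the AS241 oracle", {
  expect_equal(dprime(6, 12, 6, 12), 0)
  expect_equal(dprime(12, 12, 0, 12), 3.4634, tolerance = 1e-4)
  expect_equal(dprime(9, 12, 3, 12), 1.3490, tolerance = 1e-4)

  # agreement with an independent quantile implementation to 1e-9,
  # across all count combinations of a 12/12 block
  for (h in 0:12) {
    for (f in 0:12) {
      expected <- qnorm_oracle(clipped_rate(h, 12)) -
        qnorm_oracle(clipped_rate(f, 12))
      expect_equal(dprime(h, 12, f, 12), expected, tolerance = 1e-9)
    }
  }
})

test_that("d-prime is antisymmetric under swapping hit and false counts", {
  for (a in c(0, 3, 7, 12)) {
    for (b in c(0, 5, 12)) {
      expect_equal(dprime(a, 12, b, 12), -dprime(b, 12, a, 12))
    }
  }
})

test_that("block statistics implement the printed rate formulas", {
  outcomes <- c(rep("Hit", 10), rep("Miss", 2), rep("FalseChoice", 3),
                rep("CorrectRejection", 9))
  bs <- block_stats(outcomes, block_size = 24)
  expect_equal(bs$performance, 19 / 24)
  expect_equal(bs$hit_rate, 10 / 12)
  expect_equal(bs$false_choice_rate, 3 / 12)
  expect_equal(bs$cr_rate, 9 / 12)
  expect_equal(bs$cr_rate + bs$false_choice_rate, 1)
  expect_equal(bs$d_prime, dprime(10, 12, 3, 12))

  expect_equal(block_stats(rep(c("Hit", "CorrectRejection"), 12))$performance,
               1)
  silent <- rep(c("Miss", "CorrectRejection"), 12)
  expect_equal(block_stats(silent)$performance, 0.5)
  expect_equal(block_stats(silent)$hit_rate, 0)

  # totals conserve within every complete block
  set.seed(1)
  long <- sample(c("Hit", "Miss", "FalseChoice", "CorrectRejection"), 96,
                 replace = TRUE)
  bs2 <- block_stats(long, 24)
  expect_true(all(bs2$hit + bs2$miss + bs2$false_choice +
                    bs2$correct_rejection == 24))
  # trailing partial block is reported but flagged
  bs3 <- block_stats(long[1:30], 24)
  expect_equal(bs3$complete, c(TRUE, FALSE))
  expect_equal(bs3$n, c(24L, 6L))

  expect_error(block_stats(character(0)), "nonempty")
  expect_error(block_stats(c("Hit", "Banana")), "unknown outcome")
})

test_that("licking efficiency counts pump-triggering licks as rewarded", {
  mk <- function(lick_t, pump_t) {
    data.frame(t_ms = as.integer(c(lick_t, pump_t)),
               kind = c(rep("lick_on", length(lick_t)),
                        rep("pump_on", length(pump_t))),
               stringsAsFactors = FALSE)
  }
  # 30 rewarded of 40 licks
  ev <- mk(seq(100, by = 100, length.out = 40),
           seq(100, by = 100, length.out = 30))
  expect_equal(licking_efficiency(ev), 0.75)
  ev2 <- mk(c(100, 200), c(100, 200))
  expect_equal(licking_efficiency(ev2), 1)
  expect_error(licking_efficiency(mk(integer(0), 100)), "no licks")

  # in an engine run, rewarded licks are exactly the hit triggers
  rec <- run_task_session(default_config("GNG"), continuous_licker(),
                          seed = 1, n_trials = 24)
  n_licks <- sum(rec$events$kind == "lick_on")
  expect_equal(licking_efficiency(rec), 12 / n_licks)
})

test_that("lick-rate curves bin at 100 ms and smooth with span 5", {
  # constant 10 Hz train: one lick per bin, 10 Hz flat, smoothing-invariant
  train <- seq(0.05, 0.95, by = 0.1)
  curve <- licking_rate(list(train, train), duration_s = 1)
  expect_equal(curve$rate_hz, rep(10, 10))
  expect_equal(curve$smoothed_hz, rep(10, 10))

  # a single lick in the middle bin of nine spreads to 1/5 over the span
  single <- licking_rate(list(0.45), duration_s = 0.9)
  expect_equal(length(single$rate_hz), 9L)
  expect_equal(single$rate_hz[5], 10)
  expect_equal(single$smoothed_hz[3:7], rep(2, 5))
  expect_equal(single$smoothed_hz[c(2, 8)], c(0, 0))

  # edge bins use symmetrically shrunk spans (1, 3, 5, ...)
  x <- c(1, 0, 0, 0, 0, 0, 0, 0, 2)
  sm <- odortask:::smooth_moving_average(x, 5)
  expect_equal(sm[1], 1)        # span 1 at the boundary
  expect_equal(sm[2], 1 / 3)    # span 3
  expect_equal(sm[9], 2)
  expect_equal(sm[8], 2 / 3)

  empty <- licking_rate(list(numeric(0), numeric(0)), duration_s = 0.5)
  expect_true(all(empty$rate_hz == 0))
  expect_error(licking_rate(list(0.1), span = 4), "odd")
  expect_error(licking_rate(list(0.1), bin_ms = 0), "positive")
})

test_that("trials-to-criterion matches the window-scan examples", {
  expect_equal(trials_to_criterion(rep(TRUE, 24)), 24L)
  expect_equal(trials_to_criterion(c(rep(FALSE, 4), rep(TRUE, 40))), 24L)
  expect_equal(trials_to_criterion(c(rep(FALSE, 5), rep(TRUE, 40))), 25L)
  # 19/24 is not strictly greater than 80%
  block <- c(rep(TRUE, 19), rep(FALSE, 5))
  expect_true(is.na(trials_to_criterion(rep(block, 4))))
  expect_true(is.na(trials_to_criterion(rep(FALSE, 100))))
  expect_true(is.na(trials_to_criterion(rep(TRUE, 10))))  # shorter than window
  expect_error(trials_to_criterion(rep(TRUE, 30), window = 0), "window")
  # outcome strings: Hit and CR count as correct
  expect_equal(trials_to_criterion(rep(c("Hit", "CorrectRejection"), 12)),
               24L)
})

test_that("well-trained detection needs three consecutive windows", {
  expect_true(is_well_trained(rep(TRUE, 26)))
  expect_false(is_well_trained(rep(TRUE, 25)))
  expect_false(is_well_trained(rep(c(TRUE, FALSE), 50)))
  # exactly 19/24 in every window: never strictly above
  expect_false(is_well_trained(rep(c(rep(TRUE, 19), rep(FALSE, 5)), 4)))
})

test_that("criterion scans agree with the brute-force oracle", {
  set.seed(123)
  for (i in 1:200) {
    p <- stats::runif(1, 0.5, 0.95)
    ok <- stats::runif(60) < p
    expect_identical(trials_to_criterion(ok), ttc_oracle(ok))
    expect_identical(is_well_trained(ok), well_trained_oracle(ok))
  }
})
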