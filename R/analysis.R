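# Behavioral statistics computed from classified trial outcomes and event
# logs: blocked performance and rates, d-prime with extreme-rate clipping,
# licking efficiency, binned/smoothed lick-rate curves, and the
# trials-to-criterion / well-trained measures.

OUTCOMES <- c("Hit", "Miss", "FalseChoice", "CorrectRejection")

#' Clip an extreme response rate away from 0 and 1
#'
#' Converts a count ratio `k/n` into a rate safe for the normal quantile:
#' a rate of 100% is set to `1 - 1/(2n)` and a rate of zero to `1/(2n)`,
#' with `n` the number of possible trials of that side. Intermediate rates
#' pass through unchanged. This is the standard correction that keeps
#' d-prime finite.
#'
#' @param k number of response trials (hits or false choices), `0 <= k <= n`.
#' @param n number of possible trials of that type, `n >= 1`.
#' @return clipped rate, strictly inside `(0, 1)`.
#' @examples
#' clipped_rate(12, 12)  # 23/24
#' clipped_rate(0, 12)   # 1/24
#' @export
clipped_rate <- function(k, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("rate undefined: n must be at least 1", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > n) {
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  }
  if (k == n) return(1 - 1 / (2 * n))
  if (k == 0) return(1 / (2 * n))
  k / n
}

#' Discriminability (d-prime) from hit and false-choice counts
#'
#' `d' = qnorm(hit rate) - qnorm(false-choice rate)`, with each rate first
#' clipped by [clipped_rate()] using its own side's trial count, so perfect
#' or empty blocks stay finite.
#'
#' @param hit_k,hit_n hit count and number of go trials.
#' @param fc_k,fc_n false-choice count and number of no-go trials.
#' @return d-prime (dimensionless).
#' @examples
#' dprime(12, 12, 0, 12)  # ~3.46
#' dprime(9, 12, 3, 12)   # ~1.35
#' @export
dprime <- function(hit_k, hit_n, fc_k, fc_n) {
  stats::qnorm(clipped_rate(hit_k, hit_n)) -
    stats::qnorm(clipped_rate(fc_k, fc_n))
}

#' Per-block counts, rates and d-prime
#'
#' Bins an ordered outcome sequence into consecutive blocks (default 24
#' trials, divisible by the 4 odor-sequence types of the two-odor tasks)
#' and computes, per block: outcome counts, performance
#' `(hits + correct rejections) / total`, hit rate `hit/(hit+miss)`,
#' false-choice and correct-rejection rates over no-go trials, and d-prime
#' with per-block clipping counts. An incomplete trailing block is reported
#' and flagged in the `complete` column.
#'
#' @param outcomes character vector of trial outcomes in
#'   `c("Hit","Miss","FalseChoice","CorrectRejection")`, in trial order.
#' @param block_size trials per block, at least 1.
#' @return data frame with one row per block: `block`, `n`, `hit`, `miss`,
#'   `false_choice`, `correct_rejection`, `n_go`, `n_nogo`, `performance`,
#'   `hit_rate`, `false_choice_rate`, `cr_rate`, `d_prime`, `complete`.
#'   Rates over an empty side are `NA`.
#' @export
block_stats <- function(outcomes, block_size = 24) {
  if (!length(outcomes)) stop("outcomes must be nonempty", call. = FALSE)
  if (block_size < 1) stop("block_size must be at least 1", call. = FALSE)
  bad <- setdiff(unique(outcomes), OUTCOMES)
  if (length(bad)) {
    stop("unknown outcome(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(outcomes)
  block_of <- (seq_len(n) - 1L) %/% block_size + 1L
  blocks <- unique(block_of)
  rows <- lapply(blocks, function(b) {
    o <- outcomes[block_of == b]
    hit <- sum(o == "Hit"); miss <- sum(o == "Miss")
    fc <- sum(o == "FalseChoice"); cr <- sum(o == "CorrectRejection")
    n_go <- hit + miss; n_nogo <- fc + cr
    data.frame(
      block = b, n = length(o), hit = hit, miss = miss, false_choice = fc,
      correct_rejection = cr, n_go = n_go, n_nogo = n_nogo,
      performance = (hit + cr) / length(o),
      hit_rate = if (n_go > 0) hit / n_go else NA_real_,
      false_choice_rate = if (n_nogo > 0) fc / n_nogo else NA_real_,
      cr_rate = if (n_nogo > 0) cr / n_nogo else NA_real_,
      d_prime = if (n_go > 0 && n_nogo > 0) {
        dprime(hit, n_go, fc, n_nogo)
      } else NA_real_,
      complete = length(o) == block_size,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Licking efficiency of a session
#'
#' The fraction of licks that resulted in a water reward:
#' `rewarded / (rewarded + unrewarded)`. A lick counts as rewarded when it
#' triggered a pump delivery, i.e. its `lick_on` timestamp coincides with a
#' `pump_on` event; every other lick is unrewarded. Program-controlled
#' deliveries that no lick triggered reward no lick.
#'
#' @param record a `session_record`, or an event-log data frame with
#'   columns `t_ms` and `kind`.
#' @return efficiency in `[0, 1]`; a session without any lick has no
#'   defined efficiency and raises an error.
#' @export
licking_efficiency <- function(record) {
  events <- if (inherits(record, "session_record")) record$events else record
  licks <- events$t_ms[events$kind == "lick_on"]
  if (!length(licks)) {
    stop("licking efficiency is undefined for a session with no licks",
         call. = FALSE)
  }
  pumps <- events$t_ms[events$kind == "pump_on"]
  rewarded <- sum(licks %in% pumps)
  rewarded / length(licks)
}

# centered moving average with symmetric window shrink at the edges
# (effective spans 1, 3, 5, ..., span, ..., 5, 3, 1), the documented edge
# behavior of the classic smoothing routine
smooth_moving_average <- function(x, span = 5) {
  if (span %% 2 == 0) stop("span must be odd", call. = FALSE)
  n <- length(x)
  half <- (span - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Trial-aligned lick-rate curve
#'
#' Bins lick times (relative to trial start) into fixed-width bins (100 ms),
#' averages counts across trials, converts to Hz, and smooths with a
#' centered moving average (span 5 bins, shrinking symmetrically at the
#' edges). A constant lick rate is invariant under the smoothing.
#'
#' @param lick_times_by_trial list with one numeric vector of lick times
#'   (seconds from trial start) per trial.
#' @param duration_s curve extent in seconds; defaults to covering the
#'   latest lick.
#' @param bin_ms bin width in milliseconds.
#' @param span odd smoothing span in bins.
#' @return an object of class `lick_rate_curve`: list with `bin_edges_s`,
#'   `t_mid_s`, `rate_hz` (raw) and `smoothed_hz`.
#' @export
licking_rate <- function(lick_times_by_trial, duration_s = NULL,
                         bin_ms = 100, span = 5) {
  stopifnot(is.list(lick_times_by_trial), length(lick_times_by_trial) > 0)
  if (bin_ms <= 0) stop("bin_ms must be positive", call. = FALSE)
  if (span %% 2 == 0) stop("span must be odd", call. = FALSE)
  all_licks <- unlist(lick_times_by_trial)
  if (is.null(duration_s)) {
    duration_s <- if (length(all_licks)) max(all_licks) + bin_ms / 1000 else
      bin_ms / 1000
  }
  n_bins <- max(1L, ceiling(duration_s * 1000 / bin_ms))
  edges <- seq(0, by = bin_ms / 1000, length.out = n_bins + 1L)
  counts <- matrix(0, nrow = length(lick_times_by_trial), ncol = n_bins)
  for (i in seq_along(lick_times_by_trial)) {
    lt <- lick_times_by_trial[[i]]
    lt <- lt[lt >= 0 & lt < edges[n_bins + 1L]]
    if (length(lt)) {
      idx <- pmin(n_bins, floor(lt * 1000 / bin_ms) + 1L)
      tab <- tabulate(idx, nbins = n_bins)
      counts[i, ] <- tab
    }
  }
  mean_counts <- colMeans(counts)
  rate <- mean_counts * 1000 / bin_ms
  out <- list(bin_edges_s = edges, t_mid_s = (edges[-1L] + edges[-n_bins - 1L]) / 2,
              rate_hz = rate, smoothed_hz = smooth_moving_average(rate, span))
  class(out) <- "lick_rate_curve"
  out
}

#' @export
print.lick_rate_curve <- function(x, ...) {
  cat("<lick_rate_curve>", length(x$rate_hz), "bins of",
      round(diff(x$bin_edges_s[1:2]) * 1000), "ms; peak",
      round(max(x$smoothed_hz), 2), "Hz (smoothed)\n")
  invisible(x)
}

# logical correctness sequence from outcomes (Hit and CR are correct)
correct_sequence <- function(outcomes) {
  if (is.logical(outcomes)) return(outcomes)
  bad <- setdiff(unique(outcomes), OUTCOMES)
  if (length(bad)) {
    stop("unknown outcome(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  outcomes %in% c("Hit", "CorrectRejection")
}

#' Number of trials to reach the learning criterion
#'
#' Scans a sliding window (stride 1) of `window` consecutive trials and
#' returns the 1-based index of the final trial of the first window whose
#' correct fraction is strictly greater than `rate` (the criterion is
#' "larger than 80%": 20/24 qualifies, 19/24 does not). The minimum
#' attainable value is therefore `window`. When no window qualifies the
#' session did not reach criterion (NRC) and `NA` is returned.
#'
#' @param outcomes outcome strings (Hit/CR count as correct) or a logical
#'   correctness vector, in trial order.
#' @param rate criterion correct rate (strict lower bound).
#' @param window window length in trials, at least 1.
#' @return integer index of the qualifying window's last trial, or
#'   `NA_integer_` for NRC.
#' @examples
#' trials_to_criterion(rep(TRUE, 24))                    # 24
#' trials_to_criterion(c(rep(FALSE, 5), rep(TRUE, 30)))  # 25
#' @export
trials_to_criterion <- function(outcomes, rate = 0.80, window = 24) {
  if (window < 1) stop("window must be at least 1", call. = FALSE)
  ok <- correct_sequence(outcomes)
  n <- length(ok)
  if (n < window) return(NA_integer_)
  cs <- cumsum(c(0L, ok))
  wins <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  hit <- which(wins > rate)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1L] + window - 1L)
}

#' Well-trained detection
#'
#' A subject counts as well trained when three (by default) consecutive
#' sliding-window positions each have a correct rate strictly above the
#' criterion — i.e. windows ending at trials `t`, `t+1`, `t+2` all exceed
#' `rate`.
#'
#' @inheritParams trials_to_criterion
#' @param consecutive number of consecutive qualifying windows required.
#' @return logical.
#' @export
is_well_trained <- function(outcomes, rate = 0.80, window = 24,
                            consecutive = 3) {
  if (window < 1) stop("window must be at least 1", call. = FALSE)
  ok <- correct_sequence(outcomes)
  n <- length(ok)
  if (n < window + consecutive - 1L) return(FALSE)
  cs <- cumsum(c(0L, ok))
  wins <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  qual <- wins > rate
  if (length(qual) < consecutive) return(FALSE)
  run <- 0L
  for (q in qual) {
    run <- if (q) run + 1L else 0L
    if (run >= consecutive) return(TRUE)
  }
  FALSE
}
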