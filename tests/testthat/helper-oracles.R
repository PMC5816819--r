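# Independent oracles used by the tests; deliberately separate from the
# package's implementation paths.

# Standard-normal quantile via the AS 241 rational approximation (Wichura),
# accurate to ~1e-15; independent of stats::qnorm.
qnorm_oracle <- function(p) {
  stopifnot(p > 0, p < 1)
  q <- p - 0.5
  if (abs(q) <= 0.425) {
    r <- 0.180625 - q * q
    num <- (((((((2509.0809287301226727 * r + 33430.575583588128105) * r +
      67265.770927008700853) * r + 45921.953931549871457) * r +
      13731.693765509461125) * r + 1971.5909503065514427) * r +
      133.14166789178437745) * r + 3.387132872796366608)
    den <- (((((((5226.495278852545703 * r + 28729.085735721942674) * r +
      39307.89580009271061) * r + 21213.794301586595867) * r +
      5394.1960214247511077) * r + 687.1870074920579083) * r +
      42.313330701600911252) * r + 1)
    return(q * num / den)
  }
  r <- if (q < 0) p else 1 - p
  r <- sqrt(-log(r))
  if (r <= 5) {
    r <- r - 1.6
    num <- (((((((7.7454501427834140764e-4 * r + 0.0227238449892691845833) *
      r + 0.24178072517745061177) * r + 1.27045825245236838258) * r +
      3.64784832476320460504) * r + 5.7694972214606914055) * r +
      4.6303378461565452959) * r + 1.42343711074968357734)
    den <- (((((((1.05075007164441684324e-9 * r + 5.475938084995344946e-4) *
      r + 0.0151986665636164571966) * r + 0.14810397642748007459) * r +
      0.68976733498510000455) * r + 1.6763848301838038494) * r +
      2.05319162663775882187) * r + 1)
  } else {
    r <- r - 5
    num <- (((((((2.01033439929228813265e-7 * r +
      2.71155556874348757815e-5) * r + 0.0012426609473880784386) * r +
      0.026532189526576123093) * r + 0.29656057182850489123) * r +
      1.7848265399172913358) * r + 5.4637849111641143699) * r +
      6.6579046435011037772)
    den <- (((((((2.04426310338993978564e-15 * r +
      1.4215117583164458887e-7) * r + 1.8463183175100546818e-5) * r +
      7.868691311456132591e-4) * r + 0.0148753612908506148525) * r +
      0.13692988092273580531) * r + 0.59983220655588793769) * r + 1)
  }
  val <- num / den
  if (q < 0) -val else val
}

# brute-force sliding-window scans for the criterion measures
ttc_oracle <- function(ok, rate = 0.8, window = 24) {
  n <- length(ok)
  if (n < window) return(NA_integer_)
  for (end in window:n) {
    if (mean(ok[(end - window + 1):end]) > rate) return(end)
  }
  NA_integer_
}

well_trained_oracle <- function(ok, rate = 0.8, window = 24,
                                consecutive = 3) {
  n <- length(ok)
  if (n < window + consecutive - 1) return(FALSE)
  for (end in window:(n - consecutive + 1)) {
    all_ok <- TRUE
    for (j in 0:(consecutive - 1)) {
      if (mean(ok[(end - window + 1 + j):(end + j)]) <= rate) {
        all_ok <- FALSE
        break
      }
    }
    if (all_ok) return(TRUE)
  }
  FALSE
}

# event timing pulled straight from a log (independent of the engine's
# bookkeeping): gaps between consecutive trials, odor pulse lengths,
# sample-offset-to-test-onset delays
log_timing <- function(events) {
  starts <- events$t_ms[events$kind == "trial_start"]
  ends <- events$t_ms[events$kind == "trial_end"]
  ons <- events$t_ms[events$kind == "odor_on"]
  offs <- events$t_ms[events$kind == "odor_off"]
  list(starts = starts, ends = ends,
       pulses = offs - ons,
       itis = if (length(starts) > 1) starts[-1] - ends[-length(ends)]
       else numeric(0))
}

# agent that licks mid-window only during program-teaching trials
teaching_only_licker <- function() {
  odortask:::new_lick_agent("teaching_only", decide = function(ctx) {
    if (!is.null(ctx$window) && identical(ctx$mode, "program_teaching")) {
      mean(ctx$window)
    } else numeric(0)
  })
}

ALL_PARADIGMS <- c("DNMS", "DPA", "GNG", "GNG_REV")
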