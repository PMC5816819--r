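# First-order kinetic model of the odor concentration delivered by the
# olfactometer. The delivery line is characterized by two measured constants
# per odorant: the rising latency L95 (time after valve opening to reach 95%
# of the concentration plateau) and the decay time constant tau_d (time after
# valve closing to fall to 1/e of the level at closure). A single exponential
# per phase reproduces both; the implied rise time constant is
# tau_r = L95 / ln(20), since 1 - exp(-L95/tau_r) = 0.95.

#' Measured delivery kinetics of the stock odorant panel
#'
#' PID-characterized rise/decay constants for the four odorants used across
#' the tasks, with their relative volume ratios in the carrier air (set by
#' each odorant's vapor pressure).
#'
#' @return data frame with columns `odorant`, `ratio_pct`,
#'   `rise_latency_ms` (time to 95% of plateau) and `decay_tau_ms`
#'   (time to 1/e of plateau after valve close).
#' @export
odorant_panel <- function() {
  data.frame(
    odorant = c("1-Butanol", "Methyl butyrate", "Hexanoic acid", "Octane"),
    ratio_pct = c(10, 2.5, 15, 5),
    rise_latency_ms = c(18, 17, 31, 71),
    decay_tau_ms = c(20, 22, 41, 31),
    stringsAsFactors = FALSE
  )
}

#' Calibrate odor-delivery kinetics from measured constants
#'
#' Converts a measured 95% rise latency and 1/e decay constant into the
#' two-exponential kinetics object used by [concentration_trace()] and
#' [time_to_fraction()]. The concentration plateau is normalized to 1
#' (PID readouts are relative); the volume ratio is carried as metadata.
#'
#' @param name odorant name; when `ratio`, `L95_ms` or `decay_tau_ms` are
#'   omitted and the name matches the stock panel, the panel values are used.
#' @param ratio relative volume ratio of saturated vapor in carrier air (%).
#' @param L95_ms rise latency to 95% of plateau, ms; must be positive.
#' @param decay_tau_ms decay time constant (1/e), ms; must be positive.
#' @return an object of class `odor_kinetics` with fields `odorant`,
#'   `ratio_pct`, `rise_latency_ms`, `decay_tau_ms` and the derived
#'   `rise_tau_ms = L95_ms / log(20)`.
#' @examples
#' k <- calibrate_kinetics("1-Butanol")
#' k$rise_tau_ms  # 18 / log(20) ~ 6.01 ms
#' @export
calibrate_kinetics <- function(name, ratio = NULL, L95_ms = NULL,
                               decay_tau_ms = NULL) {
  if (is.null(L95_ms) || is.null(decay_tau_ms) || is.null(ratio)) {
    panel <- odorant_panel()
    row <- panel[panel$odorant == name, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("odorant '", name, "' is not in the stock panel; supply ratio, ",
           "L95_ms and decay_tau_ms explicitly", call. = FALSE)
    }
    if (is.null(ratio)) ratio <- row$ratio_pct
    if (is.null(L95_ms)) L95_ms <- row$rise_latency_ms
    if (is.null(decay_tau_ms)) decay_tau_ms <- row$decay_tau_ms
  }
  if (!is.numeric(L95_ms) || L95_ms <= 0) {
    stop("L95_ms must be positive", call. = FALSE)
  }
  if (!is.numeric(decay_tau_ms) || decay_tau_ms <= 0) {
    stop("decay_tau_ms must be positive", call. = FALSE)
  }
  k <- list(odorant = name, ratio_pct = ratio,
            rise_latency_ms = L95_ms, decay_tau_ms = decay_tau_ms,
            rise_tau_ms = L95_ms / log(20))
  class(k) <- "odor_kinetics"
  k
}

#' @export
print.odor_kinetics <- function(x, ...) {
  cat(sprintf(
    "<odor_kinetics> %s (%g%% vapor): rise L95 = %g ms (tau_r = %.3f ms), decay tau = %g ms\n",
    x$odorant, x$ratio_pct, x$rise_latency_ms, x$rise_tau_ms,
    x$decay_tau_ms))
  invisible(x)
}

#' Relative odor-concentration trace for one valve cycle
#'
#' Evaluates the piecewise first-order response on a time grid: zero before
#' the valve opens, `1 - exp(-(t - open)/tau_r)` while open, and
#' exponential decay `c(close) * exp(-(t - close)/tau_d)` after closure.
#' Repeated valve cycles with the same kinetics produce identical traces —
#' the model has no adaptation term, matching the observed trial-to-trial
#' stability of delivered concentration.
#'
#' @param kinetics an `odor_kinetics`.
#' @param valve_open_ms,valve_close_ms valve open/close times (ms),
#'   `valve_open_ms < valve_close_ms`.
#' @param t_grid sorted numeric vector of evaluation times (ms).
#' @return numeric vector of relative concentrations in `[0, 1]`.
#' @export
concentration_trace <- function(kinetics, valve_open_ms, valve_close_ms,
                                t_grid) {
  stopifnot(inherits(kinetics, "odor_kinetics"),
            valve_open_ms < valve_close_ms)
  if (is.unsorted(t_grid)) stop("t_grid must be sorted", call. = FALSE)
  tau_r <- kinetics$rise_tau_ms
  tau_d <- kinetics$decay_tau_ms
  c_close <- 1 - exp(-(valve_close_ms - valve_open_ms) / tau_r)
  out <- numeric(length(t_grid))
  open_phase <- t_grid >= valve_open_ms & t_grid < valve_close_ms
  decay_phase <- t_grid >= valve_close_ms
  out[open_phase] <- 1 - exp(-(t_grid[open_phase] - valve_open_ms) / tau_r)
  out[decay_phase] <- c_close * exp(-(t_grid[decay_phase] - valve_close_ms) /
                                      tau_d)
  out
}

#' Time for the modeled concentration to reach a fraction of plateau
#'
#' Inverts the phase's exponential: on the rise, the time after valve
#' opening to reach `fraction` of plateau is `-tau_r * log(1 - fraction)`;
#' on the decay, the time after closure to fall to `fraction` of the level
#' at closure is `-tau_d * log(fraction)`. By construction,
#' `time_to_fraction(k, 0.95, "rise")` recovers the calibrated rise latency
#' and `time_to_fraction(k, exp(-1), "decay")` the decay constant.
#'
#' @param kinetics an `odor_kinetics`.
#' @param fraction target fraction, strictly inside `(0, 1)`.
#' @param phase `"rise"` or `"decay"`.
#' @return time in ms.
#' @examples
#' time_to_fraction(calibrate_kinetics("Hexanoic acid"), 0.95, "rise")  # 31
#' @export
time_to_fraction <- function(kinetics, fraction, phase = c("rise", "decay")) {
  stopifnot(inherits(kinetics, "odor_kinetics"))
  phase <- match.arg(phase)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (phase == "rise") {
    -kinetics$rise_tau_ms * log(1 - fraction)
  } else {
    -kinetics$decay_tau_ms * log(fraction)
  }
}
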