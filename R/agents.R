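# Simulated mouse policies. The engines are agnostic to what produces licks;
# an agent is an environment of class "lick_agent" exposing
#   reset(seed)  — reinitialize internal state at session start
#   decide(ctx)  — lick times (seconds, relative to trial/bout start) for one
#                  trial slot or teaching bout
#   update(outcome, rewarded) — learning signal after a classified trial
# ctx carries: phase ("task"/"shaping"/"teach"), paradigm, trial index,
# seq_key (odor-sequence identity), trial_type, window (response window in
# seconds relative to slot start, NULL for teaching bouts), slot_s (slot
# duration including the inter-trial interval), t_start_s (absolute time),
# and mode (shaping mode). Agents draw randomness from the session RNG
# stream, so a (config, agent, seed) triple is fully deterministic.

new_lick_agent <- function(name, params = list(), reset = NULL,
                           decide, update = NULL) {
  agent <- new.env(parent = emptyenv())
  agent$name <- name
  agent$params <- params
  agent$reset <- if (is.null(reset)) function(seed) invisible(NULL) else reset
  agent$decide <- decide
  agent$update <- if (is.null(update)) {
    function(outcome, rewarded) invisible(NULL)
  } else update
  class(agent) <- "lick_agent"
  agent
}

#' @export
print.lick_agent <- function(x, ...) {
  p <- if (length(x$params)) {
    paste0(" (", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = ", "), ")")
  } else ""
  cat("<lick_agent> ", x$name, p, "\n", sep = "")
  invisible(x)
}

#' Agent that never licks
#'
#' The degenerate policy: every go trial is a Miss, every no-go trial a
#' Correct Rejection, so balanced blocks score exactly 0.5.
#'
#' @return a `lick_agent`.
#' @export
silent_agent <- function() {
  new_lick_agent("silent", decide = function(ctx) numeric(0))
}

#' Agent that licks continuously at a fixed rate
#'
#' Licks on a fixed session-wide grid (default 8 Hz, a typical rodent
#' licking rate), through trials and inter-trial intervals alike. Whenever
#' the response window is at least one inter-lick interval long this
#' guarantees an in-window lick, so every go trial is a Hit and every no-go
#' trial a False Choice.
#'
#' @param rate_hz licks per second; must be positive.
#' @return a `lick_agent`.
#' @export
continuous_licker <- function(rate_hz = 8) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz must be a positive number", call. = FALSE)
  }
  period <- 1 / rate_hz
  new_lick_agent(
    "continuous_licker", params = list(rate_hz = rate_hz),
    decide = function(ctx) {
      t0 <- ctx$t_start_s
      t1 <- t0 + ctx$slot_s
      k <- seq(from = ceiling(t0 / period), to = floor((t1 - 1e-9) / period))
      k <- k[k * period >= t0 & k * period < t1]
      k * period - t0
    }
  )
}

#' Agent that licks with a fixed probability per trial type
#'
#' On every trial, emits a single lick at the middle of the response window
#' with the probability configured for that trial's type. Probabilities of
#' 1 and 0 for go/no-go give the perfect agent; equal probabilities give
#' chance performance.
#'
#' @param p_lick_by_type named numeric vector with entries `go` and `nogo`,
#'   each in `[0, 1]`. A single unnamed probability applies to both types.
#' @return a `lick_agent`.
#' @export
bernoulli_agent <- function(p_lick_by_type = c(go = 0.5, nogo = 0.5)) {
  p <- p_lick_by_type
  if (length(p) == 1L && is.null(names(p))) p <- c(go = p[[1]], nogo = p[[1]])
  if (!all(c("go", "nogo") %in% names(p))) {
    stop("p_lick_by_type needs entries named 'go' and 'nogo'", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("lick probabilities must lie in [0, 1]", call. = FALSE)
  }
  new_lick_agent(
    "bernoulli", params = as.list(p),
    decide = function(ctx) {
      if (is.null(ctx$window)) return(numeric(0))  # teaching bouts: no policy
      if (stats::runif(1) < p[[ctx$trial_type]]) {
        mean(ctx$window)
      } else numeric(0)
    }
  )
}

#' Delta-rule (Rescorla-Wagner) learning agent
#'
#' Maintains a value estimate `V` per odor-sequence type, initialized at
#' `p0`, and licks once mid-window with probability `V`. After a trial on
#' which it licked, the estimate moves toward the reward outcome:
#' `V <- V + alpha * (r - V)` with `r = 1` if the lick was rewarded and `0`
#' otherwise. Trials without a lick leave `V` unchanged — the tasks deliver
#' no feedback for withheld licks (no punishment), so a learner gated on
#' responding is the minimal consistent model. Go-sequence values climb to
#' ceiling while no-go values decay, which qualitatively reproduces rising
#' performance with a ceiling hit rate; after a contingency reversal the
#' same dynamics produce a performance dip and recovery.
#'
#' @param alpha learning rate in `(0, 1]`.
#' @param p0 initial value (and baseline lick probability) in `(0, 1)`.
#' @return a `lick_agent`.
#' @export
delta_rule_learner <- function(alpha = 0.1, p0 = 0.6) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1) {
    stop("p0 must lie in (0, 1)", call. = FALSE)
  }
  V <- new.env(parent = emptyenv())
  last <- new.env(parent = emptyenv())
  agent <- new_lick_agent(
    "delta_rule", params = list(alpha = alpha, p0 = p0),
    reset = function(seed) {
      rm(list = ls(V), envir = V)
      last$licked <- FALSE
      last$key <- NULL
      invisible(NULL)
    },
    decide = function(ctx) {
      if (is.null(ctx$window)) return(numeric(0))
      key <- ctx$seq_key
      if (is.null(V[[key]])) V[[key]] <- p0
      licked <- stats::runif(1) < V[[key]]
      last$licked <- licked
      last$key <- key
      if (licked) mean(ctx$window) else numeric(0)
    },
    update = function(outcome, rewarded) {
      if (isTRUE(last$licked) && !is.null(last$key)) {
        r <- if (isTRUE(rewarded)) 1 else 0
        V[[last$key]] <- V[[last$key]] + alpha * (r - V[[last$key]])
      }
      invisible(NULL)
    }
  )
  agent$values <- function() {
    keys <- ls(V)
    stats::setNames(vapply(keys, function(k) V[[k]], numeric(1)), keys)
  }
  agent
}

#' Construct an agent by name
#'
#' Dispatch used by the command-line interface: maps an agent name and a
#' flat parameter list to the corresponding constructor.
#'
#' @param name one of `"silent"`, `"continuous"`, `"bernoulli"`, `"delta"`.
#' @param params named list of constructor arguments (e.g. `rate_hz`,
#'   `p_go`, `p_nogo`, `alpha`, `p0`).
#' @return a `lick_agent`.
#' @export
make_agent <- function(name, params = list()) {
  switch(name,
    silent = silent_agent(),
    continuous = do.call(continuous_licker, params),
    bernoulli = {
      p <- c(go = params$p_go %||% 0.5, nogo = params$p_nogo %||% 0.5)
      bernoulli_agent(p)
    },
    delta = delta_rule_learner(alpha = params$alpha %||% 0.1,
                               p0 = params$p0 %||% 0.6),
    stop("unknown agent '", name,
         "'; valid: silent, continuous, bernoulli, delta", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
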