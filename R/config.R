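#' @keywords internal
"_PACKAGE"

# Canonical paradigm identifiers. GNG_REV shares GNG timing; only the
# cue-reward contingency differs.
PARADIGMS <- c("DNMS", "DPA", "GNG", "GNG_REV")

# Event vocabulary for session logs.
EVENT_KINDS <- c(
  "lick_on", "lick_off", "odor_on", "odor_off", "pump_on", "pump_off",
  "port_forward", "port_back", "trial_start", "trial_end", "session_end"
)

#' Default session configuration for a training paradigm
#'
#' Builds the full parameter set of one training session with the published
#' defaults for the requested paradigm: a 1-s odor pulse, a 4-5 s (DNMS) or
#' 8-9 s (DPA) delay between sample and test odor, a response window of
#' 0.5-1.5 s after second-odor offset (0.5-1.0 s for DPA), fixed inter-trial
#' intervals of 10/16/5 s (DNMS/DPA/GNG), ~5 uL water per hit, 24-trial
#' blocks, and the criterion of a correct rate above 80% in a sliding
#' 24-trial window (three consecutive windows for "well trained").
#' Lick-teaching and shaping parameters (10 uL bout opener, 4 uL per three
#' licks, 2-s quiet timeout, 200 uL bout cap, 400 uL session target; switch
#' to program teaching after 5 misses within 30 trials, 100-hit daily
#' target) are included so one object configures every phase.
#'
#' @param paradigm one of `"DNMS"`, `"DPA"`, `"GNG"`, `"GNG_REV"`.
#' @return an object of class `session_config`: a named list of all
#'   protocol parameters. Durations are in seconds, volumes in microliters.
#' @examples
#' cfg <- default_config("DNMS")
#' cfg$iti_s          # 10
#' cfg$delay_range_s  # c(4, 5)
#' @export
default_config <- function(paradigm) {
  if (length(paradigm) != 1L || !is.character(paradigm) ||
      !(paradigm %in% PARADIGMS)) {
    stop("unknown paradigm ", deparse(substitute(paradigm)),
         "; valid options are: ", paste(PARADIGMS, collapse = ", "),
         call. = FALSE)
  }
  delay <- switch(paradigm,
    DNMS = c(4, 5),
    DPA  = c(8, 9),
    GNG  = NULL,
    GNG_REV = NULL
  )
  window <- if (paradigm == "DPA") c(0.5, 1.0) else c(0.5, 1.5)
  iti <- switch(paradigm, DNMS = 10, DPA = 16, GNG = 5, GNG_REV = 5)

  cfg <- list(
    paradigm = paradigm,
    odor_duration_s = 1,
    delay_range_s = delay,
    response_window_s = window,
    iti_s = iti,
    reward_uL_per_hit = 5,
    block_size = 24L,
    criterion_rate = 0.80,
    criterion_window = 24L,
    criterion_consecutive = 3L,
    # lick-teaching phase
    initial_bout_uL = 10,
    drop_uL = 4,
    licks_per_drop = 3L,
    bout_quiet_timeout_s = 2,
    bout_volume_cap_uL = 200,
    session_volume_target_uL = 400,
    max_bouts = 20L,
    inter_bout_gap_s = 1,
    # shaping phase
    miss_count_trigger = 5L,
    miss_window_trials = 30L,
    daily_hit_target = 100L,
    # safety caps (pathological agents must not hang a session)
    max_trials = 1000L,
    max_session_s = 7200,
    # hardware-style event plumbing
    lick_duration_ms = 30L,
    pump_pulse_ms = 50L
  )
  class(cfg) <- "session_config"
  validate_config(cfg)
  cfg
}

#' Validate a session configuration
#'
#' Checks the structural invariants every engine entry point assumes: all
#' durations positive, criterion rate strictly inside (0, 1), a well-formed
#' response window, and a block size divisible by the paradigm's number of
#' odor-sequence types (4 for DNMS/DPA, 2 for GNG).
#'
#' @param cfg a `session_config`.
#' @return `cfg`, invisibly; errors describe the first violated invariant.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  if (!(cfg$paradigm %in% PARADIGMS)) {
    stop("invalid paradigm: ", cfg$paradigm, call. = FALSE)
  }
  pos <- c("odor_duration_s", "iti_s", "reward_uL_per_hit",
           "bout_quiet_timeout_s", "initial_bout_uL", "drop_uL",
           "bout_volume_cap_uL", "session_volume_target_uL",
           "max_session_s")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("configuration field '", f, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$delay_range_s)) {
    d <- cfg$delay_range_s
    if (length(d) != 2L || any(d <= 0) || d[1] > d[2]) {
      stop("delay_range_s must be c(lo, hi) with 0 < lo <= hi", call. = FALSE)
    }
  }
  w <- cfg$response_window_s
  if (length(w) != 2L || w[1] >= w[2]) {
    stop("response_window_s must satisfy start < end", call. = FALSE)
  }
  if (cfg$criterion_rate <= 0 || cfg$criterion_rate >= 1) {
    stop("criterion_rate must lie strictly between 0 and 1", call. = FALSE)
  }
  k <- n_sequence_types(cfg$paradigm)
  if (cfg$block_size %% k != 0L) {
    stop("block_size (", cfg$block_size, ") must be divisible by the ",
         "paradigm's ", k, " odor-sequence types", call. = FALSE)
  }
  invisible(cfg)
}

# number of distinct odor-sequence types scheduled per paradigm
n_sequence_types <- function(paradigm) {
  if (paradigm %in% c("GNG", "GNG_REV")) 2L else 4L
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config> paradigm:", x$paradigm, "\n")
  cat("  odor ", x$odor_duration_s, " s; delay ",
      if (is.null(x$delay_range_s)) "none"
      else paste(x$delay_range_s, collapse = "-"),
      " s; window [", x$response_window_s[1], ", ", x$response_window_s[2],
      ") s; ITI ", x$iti_s, " s\n", sep = "")
  cat("  reward", x$reward_uL_per_hit, "uL/hit; block", x$block_size,
      "trials; criterion >", x$criterion_rate, "over",
      x$criterion_window, "trials x", x$criterion_consecutive, "\n")
  invisible(x)
}

#' Read or write a session configuration as a flat key/value file
#'
#' The on-disk form is a flat JSON object whose keys mirror the
#' `session_config` field names exactly, so configuration files can be
#' hand-edited and diffed.
#'
#' @param cfg a `session_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `session_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_session_config(raw)
}

#' Coerce a plain list to a session configuration
#'
#' Starts from the paradigm's defaults and overlays the supplied fields, so
#' partial configuration files are valid. Unknown keys are an error.
#'
#' @param x named list containing at least `paradigm`.
#' @return a validated `session_config`.
#' @export
as_session_config <- function(x) {
  if (inherits(x, "session_config")) {
    return(validate_config(x))
  }
  if (is.null(x$paradigm)) stop("configuration needs a 'paradigm' field",
                                call. = FALSE)
  cfg <- default_config(x$paradigm)
  extra <- setdiff(names(x), names(cfg))
  if (length(extra)) {
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  int_fields <- c("block_size", "criterion_window", "criterion_consecutive",
                  "licks_per_drop", "max_bouts", "miss_count_trigger",
                  "miss_window_trials", "daily_hit_target", "max_trials",
                  "lick_duration_ms", "pump_pulse_ms")
  for (f in setdiff(names(x), "paradigm")) {
    v <- x[[f]]
    # JSON null comes back as NULL/empty (a GNG config has no delay); keep
    # the named-NULL entry without dropping it from the list
    if (is.null(v) || length(v) == 0L) {
      cfg[f] <- list(NULL)
      next
    }
    # whole numbers read from JSON simplify to integer; keep the canonical
    # storage mode per field so round trips are identical
    v <- if (f %in% int_fields) as.integer(v) else as.numeric(v)
    cfg[[f]] <- v
  }
  if (length(cfg$delay_range_s) == 0L) cfg["delay_range_s"] <- list(NULL)
  validate_config(cfg)
  cfg
}
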