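# Discrete-event engines for the three training phases. Each engine walks
# simulated time in integer milliseconds, asks the agent for licks one trial
# slot (or teaching bout) at a time, emits the corresponding hardware events,
# and classifies outcomes. All randomness (schedule shuffles, delays, agent
# draws) runs on one private RNG stream seeded from `seed`, so a
# (config, agent, seed) triple reproduces a byte-identical session record.

#' Classify a trial outcome from lick times
#'
#' Applies the response-window rule: a go trial with at least one lick in
#' the window is a Hit, with none a Miss; a no-go trial with an in-window
#' lick is a FalseChoice, with none a CorrectRejection. The window is
#' half-open `[start, end)` — a lick exactly at the start counts, exactly at
#' the end does not. Licks outside the window never change the outcome
#' (the protocol has no punishment).
#'
#' @param trial_type `"go"` or `"nogo"`.
#' @param lick_times numeric vector of lick onsets, sorted ascending, in the
#'   same time base as `window`.
#' @param window numeric length-2, `c(start, end)` of the response window.
#' @return one of `"Hit"`, `"Miss"`, `"FalseChoice"`, `"CorrectRejection"`.
#' @examples
#' classify_response("go", c(0.2, 7.9), window = c(7.5, 8.5))   # "Hit"
#' classify_response("nogo", numeric(0), c(7.5, 8.5))           # "CorrectRejection"
#' @export
classify_response <- function(trial_type, lick_times, window) {
  stopifnot(trial_type %in% c("go", "nogo"),
            length(window) == 2L, window[1] < window[2])
  if (is.unsorted(lick_times)) {
    stop("lick_times must be sorted ascending", call. = FALSE)
  }
  licked <- any(lick_times >= window[1] & lick_times < window[2])
  if (trial_type == "go") {
    if (licked) "Hit" else "Miss"
  } else {
    if (licked) "FalseChoice" else "CorrectRejection"
  }
}

ms <- function(s) as.integer(round(s * 1000))

new_session_record <- function(phase, config, seed, events, trials, totals,
                               termination_reason, partial = FALSE) {
  rec <- list(
    schema = "odortask-session/1",
    phase = phase,
    config = config,
    seed = as.integer(seed),
    events = events,
    trials = trials,
    totals = totals,
    termination_reason = termination_reason,
    partial = partial
  )
  class(rec) <- "session_record"
  rec
}

empty_trial_table <- function() {
  data.frame(index = integer(0), paradigm = character(0),
             sample_odor = character(0), test_odor = character(0),
             trial_type = character(0), delay_s = numeric(0),
             mode = character(0), outcome = character(0),
             n_licks = integer(0), reward_uL = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.session_record <- function(x, ...) {
  cat("<session_record> phase:", x$phase, " paradigm:", x$config$paradigm,
      " seed:", x$seed, "\n")
  cat("  trials:", x$totals$n_trials, " hits:", x$totals$n_hits,
      " reward:", x$totals$reward_uL, "uL\n")
  cat("  events:", nrow(x$events), " terminated by:", x$termination_reason,
      if (isTRUE(x$partial)) " [PARTIAL]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.session_record <- function(object, ...) {
  out <- list(record = object)
  if (nrow(object$trials) > 0 && object$phase == "task") {
    out$blocks <- block_stats(object$trials$outcome,
                              block_size = object$config$block_size)
    out$criterion <- trials_to_criterion(
      object$trials$outcome,
      rate = object$config$criterion_rate,
      window = object$config$criterion_window)
    out$well_trained <- is_well_trained(
      object$trials$outcome,
      rate = object$config$criterion_rate,
      window = object$config$criterion_window,
      consecutive = object$config$criterion_consecutive)
  }
  class(out) <- "summary.session_record"
  out
}

#' @export
print.summary.session_record <- function(x, ...) {
  print(x$record)
  if (!is.null(x$blocks)) {
    cat("\nPer-block statistics:\n")
    print(x$blocks, digits = 3)
    cat("\ntrials to criterion:",
        if (is.na(x$criterion)) "NRC" else x$criterion,
        " well trained:", x$well_trained, "\n")
  }
  invisible(x)
}

# --- shared per-trial emission --------------------------------------------
# Emits trial_start, odor pulse(s), agent licks, classification, reward and
# trial_end events for one trial beginning at t0 (ms). `teaching` switches on
# the program-teaching variant used by the shaping phase (port moves forward
# and water arrives automatically at window start, untriggered by licks).
run_one_trial <- function(sink, config, t0, spec, agent, phase,
                          mode = NA_character_, teaching = FALSE) {
  odor_ms <- ms(config$odor_duration_s)
  idx <- spec$index
  sink_add(sink, t0, "trial_start", trial = idx)
  sink_add(sink, t0, "odor_on", odor = spec$sample_odor, trial = idx)
  s_off <- t0 + odor_ms
  sink_add(sink, s_off, "odor_off", odor = spec$sample_odor, trial = idx)
  if (!is.na(spec$test_odor)) {
    t_on <- s_off + ms(spec$delay_s)
    t_off <- t_on + odor_ms
    sink_add(sink, t_on, "odor_on", odor = spec$test_odor, trial = idx)
    sink_add(sink, t_off, "odor_off", odor = spec$test_odor, trial = idx)
    second_off <- t_off
  } else {
    second_off <- s_off
  }
  win <- second_off + ms(config$response_window_s)   # [start, end) in ms
  trial_end <- win[2]
  slot_end <- trial_end + ms(config$iti_s)

  ctx <- list(
    phase = phase, paradigm = spec$paradigm, index = idx,
    seq_key = sequence_key(spec$sample_odor, spec$test_odor),
    trial_type = spec$trial_type,
    window = (win - t0) / 1000,
    slot_s = (slot_end - t0) / 1000,
    t_start_s = t0 / 1000,
    mode = mode
  )
  licks_rel <- sort(agent$decide(ctx))
  lick_ms <- t0 + vapply(licks_rel, ms, integer(1))
  lick_ms <- lick_ms[lick_ms >= t0 & lick_ms < slot_end]

  for (lt in lick_ms) {
    sink_add(sink, lt, "lick_on", trial = idx)
    sink_add(sink, lt + config$lick_duration_ms, "lick_off", trial = idx)
  }

  in_window <- lick_ms[lick_ms >= win[1] & lick_ms < win[2]]
  outcome <- classify_response(spec$trial_type, lick_ms, win)

  reward <- 0
  if (teaching) {
    # program-teaching: port advances, water is delivered automatically at
    # window start regardless of licking
    sink_add(sink, second_off, "port_forward", trial = idx)
    sink_add(sink, win[1], "pump_on", trial = idx,
             volume_uL = config$reward_uL_per_hit)
    sink_add(sink, win[1] + config$pump_pulse_ms, "pump_off", trial = idx)
    sink_add(sink, trial_end, "port_back", trial = idx)
    reward <- config$reward_uL_per_hit
  } else if (outcome == "Hit") {
    # lick-triggered, instantaneous delivery at the first in-window lick
    sink_add(sink, in_window[1], "pump_on", trial = idx,
             volume_uL = config$reward_uL_per_hit)
    sink_add(sink, in_window[1] + config$pump_pulse_ms, "pump_off",
             trial = idx)
    reward <- config$reward_uL_per_hit
  }
  sink_add(sink, trial_end, "trial_end", trial = idx)

  rewarded_lick <- length(in_window) > 0 && reward > 0
  agent$update(outcome, rewarded_lick)

  list(outcome = outcome, n_licks = length(lick_ms), reward_uL = reward,
       licked_in_window = length(in_window) > 0,
       trial_end = trial_end, next_t = slot_end,
       row = data.frame(index = idx, paradigm = spec$paradigm,
                        sample_odor = spec$sample_odor,
                        test_odor = spec$test_odor,
                        trial_type = spec$trial_type,
                        delay_s = spec$delay_s,
                        mode = if (teaching) "program_teaching" else mode,
                        outcome = outcome, n_licks = length(lick_ms),
                        reward_uL = reward, stringsAsFactors = FALSE))
}

# --- full task -------------------------------------------------------------

#' Run a full-task training session
#'
#' Simulates one session of the configured paradigm: balanced pseudo-random
#' blocks of go and no-go odor sequences, odor pulses separated by the
#' paradigm's delay, lick classification in the response window, an
#' instantaneous water reward at the first in-window lick of each go trial,
#' and a fixed inter-trial interval. No punishment is ever delivered.
#'
#' @param config a `session_config`.
#' @param agent a `lick_agent` (see e.g. [delta_rule_learner()]).
#' @param seed integer seed; all session randomness derives from it.
#' @param n_trials number of trials (multiple of `config$block_size`).
#' @param map optional `contingency_map` override (e.g. a reversed GNG map).
#' @param reset_agent reset the agent's internal state at session start
#'   (default). Set `FALSE` to continue a learner across sessions, e.g.
#'   running a reversal session on an agent trained under the original
#'   contingency.
#' @return a `session_record` holding the config snapshot, the event log,
#'   one trial-result row per trial, totals, and the termination reason.
#' @examples
#' rec <- run_task_session(default_config("DNMS"), silent_agent(),
#'                         seed = 1, n_trials = 24)
#' table(rec$trials$outcome)  # 12 Miss, 12 CorrectRejection
#' @export
run_task_session <- function(config, agent, seed, n_trials = 96,
                             map = NULL, reset_agent = TRUE) {
  validate_config(config)
  stopifnot(inherits(agent, "lick_agent"))
  with_private_rng(seed, {
    if (reset_agent) agent$reset(seed)
    specs <- schedule_trials(config, n_trials, map = map)
    sink <- new_event_sink()
    rows <- vector("list", nrow(specs))
    t <- 0L
    reward <- 0
    hits <- 0L
    termination <- "completed"
    partial <- FALSE
    n_done <- 0L
    for (i in seq_len(nrow(specs))) {
      res <- tryCatch(
        run_one_trial(sink, config, t, specs[i, ], agent, phase = "task"),
        error = function(e) e)
      if (inherits(res, "error")) {
        termination <- paste0("agent_error: ", conditionMessage(res))
        partial <- TRUE
        break
      }
      rows[[i]] <- res$row
      reward <- reward + res$reward_uL
      if (res$outcome == "Hit") hits <- hits + 1L
      n_done <- i
      t <- if (i < nrow(specs)) res$next_t else res$trial_end
      if (t / 1000 > config$max_session_s) {
        termination <- "max_session_duration"
        break
      }
    }
    # any licks logged into the final inter-trial interval precede shutdown
    sink_add(sink, max(t, sink$max_t), "session_end")
    trials <- if (n_done > 0L) {
      do.call(rbind, rows[seq_len(n_done)])
    } else empty_trial_table()
    rownames(trials) <- NULL
    new_session_record(
      "task", config, seed, sink_events(sink), trials,
      totals = list(n_trials = nrow(trials), n_hits = hits,
                    reward_uL = reward),
      termination_reason = termination, partial = partial)
  })
}

# --- shaping ---------------------------------------------------------------

#' Run an automatic shaping session
#'
#' The shaping phase familiarizes the animal with the task's temporal
#' structure using only rewarded (go-type) trials. Trials come in two kinds
#' that switch automatically. In *self-learning* trials the reward is
#' lick-triggered and the water port does not move. The engine switches to
#' *program-teaching* trials — port forward, water delivered automatically
#' during the response window without a lick trigger — when the animal has
#' missed `miss_count_trigger` times within the last `miss_window_trials`
#' trials (sliding window), and stays there while teaching trials are
#' missed; one in-window lick during a teaching trial switches back. The
#' session ends when the cumulative Hit count (trials with an in-window
#' lick; automatic deliveries alone do not count) reaches
#' `daily_hit_target`, or at the safety caps.
#'
#' @inheritParams run_task_session
#' @return a `session_record`; trial rows carry the `mode` each trial ran in.
#' @export
run_shaping_session <- function(config, agent, seed, map = NULL) {
  validate_config(config)
  stopifnot(inherits(agent, "lick_agent"))
  with_private_rng(seed, {
    agent$reset(seed)
    if (is.null(map)) map <- contingency_map(config$paradigm)
    go_map <- map[map$trial_type == "go", , drop = FALSE]
    sink <- new_event_sink()
    rows <- list()
    t <- 0L
    reward <- 0
    hits <- 0L
    recent <- logical(0)      # sliding record of misses (TRUE = miss)
    prev_teaching <- FALSE
    prev_teaching_missed <- FALSE
    mode <- "self_learning"
    bag <- integer(0)
    termination <- "max_trials"
    partial <- FALSE
    i <- 0L
    while (i < config$max_trials) {
      i <- i + 1L
      # mode selection: a licked teaching trial always hands the next trial
      # back to self-learning; the miss buffer governs otherwise
      if (prev_teaching) {
        mode <- if (prev_teaching_missed) "program_teaching" else
          "self_learning"
      } else {
        mode <- if (sum(utils::tail(recent, config$miss_window_trials)) >=
                    config$miss_count_trigger) "program_teaching" else
          "self_learning"
      }
      if (!length(bag)) bag <- sample(rep(seq_len(nrow(go_map)),
                                          length.out = max(2L, nrow(go_map))))
      j <- bag[1]
      bag <- bag[-1]
      delay <- if (is.null(config$delay_range_s)) 0 else
        round(stats::runif(1, config$delay_range_s[1],
                           config$delay_range_s[2]), 3)
      spec <- data.frame(index = i, paradigm = config$paradigm,
                         sample_odor = go_map$sample_odor[j],
                         test_odor = go_map$test_odor[j],
                         trial_type = "go", delay_s = delay,
                         stringsAsFactors = FALSE)
      res <- tryCatch(
        run_one_trial(sink, config, t, spec, agent, phase = "shaping",
                      mode = mode, teaching = mode == "program_teaching"),
        error = function(e) e)
      if (inherits(res, "error")) {
        termination <- paste0("agent_error: ", conditionMessage(res))
        partial <- TRUE
        break
      }
      rows[[i]] <- res$row
      reward <- reward + res$reward_uL
      missed <- !res$licked_in_window
      if (!missed) hits <- hits + 1L
      recent <- c(recent, missed)
      if (length(recent) > config$miss_window_trials) {
        recent <- utils::tail(recent, config$miss_window_trials)
      }
      prev_teaching <- mode == "program_teaching"
      prev_teaching_missed <- prev_teaching && missed
      t <- res$next_t
      if (hits >= config$daily_hit_target) {
        termination <- "hit_target"
        t <- res$trial_end
        break
      }
      if (t / 1000 > config$max_session_s) {
        termination <- "max_session_duration"
        break
      }
    }
    # any licks logged into the final inter-trial interval precede shutdown
    sink_add(sink, max(t, sink$max_t), "session_end")
    trials <- if (length(rows)) do.call(rbind, rows) else empty_trial_table()
    rownames(trials) <- NULL
    new_session_record(
      "shaping", config, seed, sink_events(sink), trials,
      totals = list(n_trials = nrow(trials), n_hits = hits,
                    reward_uL = reward),
      termination_reason = termination, partial = partial)
  })
}

# --- lick teaching ---------------------------------------------------------

#' Run an automatic lick-teaching session
#'
#' The first training phase teaches a head-fixed, water-restricted mouse to
#' lick the water port. Each teaching bout opens with a
#' `initial_bout_uL` (10 uL) delivery as the port moves forward; thereafter
#' a `drop_uL` (4 uL) drop rewards every `licks_per_drop` (3) licks. A bout
#' ends when no lick arrives for `bout_quiet_timeout_s` (2 s) or the bout's
#' delivered volume exceeds `bout_volume_cap_uL` (strictly more than
#' 200 uL), upon which the port retracts. Bouts repeat until the session
#' total reaches `session_volume_target_uL` (400 uL) or the bout/duration
#' caps fire. No odor events occur in this phase.
#'
#' @inheritParams run_task_session
#' @return a `session_record`; `totals$n_bouts` counts completed bouts and
#'   the trial table is empty (teaching has no trials).
#' @export
run_lick_teaching_session <- function(config, agent, seed) {
  validate_config(config)
  stopifnot(inherits(agent, "lick_agent"))
  with_private_rng(seed, {
    agent$reset(seed)
    sink <- new_event_sink()
    t <- 0L
    total <- 0
    n_bouts <- 0L
    bout_rows <- list()
    termination <- "max_bouts"
    timeout_ms <- ms(config$bout_quiet_timeout_s)
    pulse <- config$pump_pulse_ms
    while (n_bouts < config$max_bouts) {
      if (total >= config$session_volume_target_uL) {
        termination <- "volume_target"
        break
      }
      if (t / 1000 > config$max_session_s) {
        termination <- "max_session_duration"
        break
      }
      n_bouts <- n_bouts + 1L
      bout_start <- t
      horizon_ms <- ms(min(600, config$max_session_s - bout_start / 1000))
      sink_add(sink, bout_start, "port_forward")
      sink_add(sink, bout_start, "pump_on",
               volume_uL = config$initial_bout_uL)
      sink_add(sink, bout_start + pulse, "pump_off")
      bout_vol <- config$initial_bout_uL

      ctx <- list(phase = "teach", paradigm = config$paradigm,
                  index = n_bouts, seq_key = NA_character_,
                  trial_type = NA_character_, window = NULL,
                  slot_s = horizon_ms / 1000, t_start_s = bout_start / 1000,
                  mode = "teaching_bout")
      licks_rel <- sort(agent$decide(ctx))
      lick_ms <- bout_start + vapply(licks_rel, ms, integer(1))
      lick_ms <- lick_ms[lick_ms >= bout_start &
                           lick_ms < bout_start + horizon_ms]

      last_activity <- bout_start
      n_licks <- 0L
      bout_end <- NA_integer_
      for (lt in lick_ms) {
        if (lt - last_activity > timeout_ms) {
          bout_end <- last_activity + timeout_ms
          break
        }
        sink_add(sink, lt, "lick_on")
        sink_add(sink, lt + config$lick_duration_ms, "lick_off")
        last_activity <- lt
        n_licks <- n_licks + 1L
        if (n_licks %% config$licks_per_drop == 0L) {
          sink_add(sink, lt, "pump_on", volume_uL = config$drop_uL)
          sink_add(sink, lt + pulse, "pump_off")
          bout_vol <- bout_vol + config$drop_uL
          if (bout_vol > config$bout_volume_cap_uL) {  # strictly larger-than
            bout_end <- lt
            break
          }
        }
      }
      if (is.na(bout_end)) {
        # lick stream exhausted: quiet timeout after the last activity,
        # clipped to the bout horizon
        bout_end <- min(last_activity + timeout_ms,
                        bout_start + horizon_ms)
      }
      sink_add(sink, bout_end, "port_back")
      total <- total + bout_vol
      bout_rows[[n_bouts]] <- data.frame(
        bout = n_bouts, start_ms = bout_start, end_ms = bout_end,
        n_licks = n_licks, volume_uL = bout_vol, stringsAsFactors = FALSE)
      t <- bout_end + ms(config$inter_bout_gap_s)
    }
    if (termination == "max_bouts" &&
        total >= config$session_volume_target_uL) {
      termination <- "volume_target"
    }
    # any licks logged into the final inter-trial interval precede shutdown
    sink_add(sink, max(t, sink$max_t), "session_end")
    bouts <- if (length(bout_rows)) do.call(rbind, bout_rows) else
      data.frame(bout = integer(0), start_ms = integer(0),
                 end_ms = integer(0), n_licks = integer(0),
                 volume_uL = numeric(0), stringsAsFactors = FALSE)
    rec <- new_session_record(
      "teaching", config, seed, sink_events(sink), empty_trial_table(),
      totals = list(n_trials = 0L, n_hits = 0L, reward_uL = total,
                    n_bouts = n_bouts),
      termination_reason = termination)
    rec$bouts <- bouts
    rec
  })
}
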