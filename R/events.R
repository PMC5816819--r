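# Event logs are plain data frames with one row per timestamped hardware or
# behavioral occurrence, mirroring the serial event stream of the rig:
# odorant valve on/off, peristaltic pump on/off, licking start/end, water-port
# moves, and trial markers. Times are integer milliseconds from session start
# (integer ms avoids float drift in ordering); payload columns are NA where a
# kind carries no payload.

# mutable accumulator used by the engines; rows are collected in a list and
# materialized once, so per-trial appends stay O(1)
new_event_sink <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- vector("list", 256L)
  env$n <- 0L
  env$max_t <- 0L
  env
}

sink_add <- function(sink, t_ms, kind, odor = NA_character_,
                     trial = NA_integer_, volume_uL = NA_real_) {
  n <- sink$n + 1L
  if (n > length(sink$rows)) {
    length(sink$rows) <- 2L * length(sink$rows)
  }
  t_int <- as.integer(round(t_ms))
  sink$rows[[n]] <- list(t_ms = t_int, kind = kind,
                         odor = odor, trial = as.integer(trial),
                         volume_uL = as.numeric(volume_uL))
  sink$n <- n
  if (t_int > sink$max_t) sink$max_t <- t_int
  invisible(NULL)
}

sink_events <- function(sink) {
  rows <- sink$rows[seq_len(sink$n)]
  if (!length(rows)) return(empty_event_log())
  df <- data.frame(
    t_ms = vapply(rows, `[[`, integer(1), "t_ms"),
    kind = vapply(rows, `[[`, character(1), "kind"),
    odor = vapply(rows, `[[`, character(1), "odor"),
    trial = vapply(rows, `[[`, integer(1), "trial"),
    volume_uL = vapply(rows, `[[`, numeric(1), "volume_uL"),
    stringsAsFactors = FALSE
  )
  # stable sort: simultaneous events keep emission order
  df <- df[order(df$t_ms), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_event_log <- function() {
  data.frame(t_ms = integer(0), kind = character(0), odor = character(0),
             trial = integer(0), volume_uL = numeric(0),
             stringsAsFactors = FALSE)
}

#' Check the structural integrity of an event log
#'
#' Runs every log invariant the engines guarantee: non-negative timestamps,
#' non-decreasing time order, every `lick_on` eventually matched by a
#' `lick_off` (and never two `lick_on` in a row), and strict on/off
#' alternation of the odor valve per odor line. Validation never raises; it
#' reports.
#'
#' @param events event-log data frame with columns `t_ms`, `kind`, `odor`.
#' @return a data frame of violations with columns `index` (offending row),
#'   `rule`, and `message`; zero rows when the log is clean.
#' @examples
#' validate_event_log(data.frame(t_ms = c(100L, 50L),
#'                               kind = c("lick_on", "lick_off"),
#'                               odor = NA_character_))
#' @export
validate_event_log <- function(events) {
  viol <- list()
  add <- function(index, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(index = index, rule = rule,
                                             message = message,
                                             stringsAsFactors = FALSE)
  }
  n <- nrow(events)
  if (is.null(n) || n == 0L) {
    return(data.frame(index = integer(0), rule = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  t <- events$t_ms
  kind <- events$kind
  bad_t <- which(t < 0)
  for (i in bad_t) add(i, "negative timestamp",
                       sprintf("t_ms = %d at row %d", t[i], i))
  if (n > 1L) {
    drop <- which(diff(t) < 0) + 1L
    for (i in drop) add(i, "non-monotone timestamp",
                        sprintf("t_ms decreases from %d to %d at row %d",
                                t[i - 1L], t[i], i))
  }
  unknown <- which(!(kind %in% EVENT_KINDS))
  for (i in unknown) add(i, "unknown event kind", kind[i])

  # lick pairing: scan for on/off alternation
  lick_idx <- which(kind %in% c("lick_on", "lick_off"))
  open_at <- NA_integer_
  for (i in lick_idx) {
    if (kind[i] == "lick_on") {
      if (!is.na(open_at)) {
        add(open_at, "unterminated lick",
            sprintf("lick_on at row %d has no lick_off before row %d",
                    open_at, i))
      }
      open_at <- i
    } else {
      if (is.na(open_at)) {
        add(i, "unmatched lick_off", sprintf("lick_off at row %d", i))
      }
      open_at <- NA_integer_
    }
  }
  if (!is.na(open_at)) {
    add(open_at, "unterminated lick",
        sprintf("lick_on at row %d never closed", open_at))
  }

  # odor valve alternation per odor line
  odor_idx <- which(kind %in% c("odor_on", "odor_off"))
  if (length(odor_idx)) {
    lines <- unique(events$odor[odor_idx])
    for (od in lines) {
      idx <- odor_idx[events$odor[odor_idx] %in% od]
      state_open <- FALSE
      for (i in idx) {
        if (kind[i] == "odor_on") {
          if (state_open) add(i, "odor valve double-open",
                              sprintf("odor '%s' opened twice (row %d)", od, i))
          state_open <- TRUE
        } else {
          if (!state_open) add(i, "odor valve double-close",
                               sprintf("odor '%s' closed while closed (row %d)",
                                       od, i))
          state_open <- FALSE
        }
      }
      if (state_open) {
        add(idx[length(idx)], "odor valve left open",
            sprintf("odor '%s' never closed", od))
      }
    }
  }
  if (!length(viol)) {
    return(data.frame(index = integer(0), rule = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}
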