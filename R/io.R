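# Plain-text persistence for session records. A record is stored as three
# diff-able text files sharing one stem:
#   <stem>.events.log   line-delimited event stream (one event per line,
#                       mirroring the serial stream the rig produces)
#   <stem>.trials.csv   companion trial table
#   <stem>.summary.json provenance + config snapshot + totals
# Times are serialized as integer milliseconds; the round trip is lossless.

LOG_SCHEMA <- "odortask-session/1"

# one event <-> one line: "t_ms<TAB>kind<TAB>key=value;key=value"
serialize_log_line <- function(t_ms, kind, odor = NA, trial = NA,
                               volume_uL = NA) {
  payload <- character(0)
  if (!is.na(odor)) payload <- c(payload, paste0("odor=", odor))
  if (!is.na(trial)) payload <- c(payload, paste0("trial=", trial))
  if (!is.na(volume_uL)) {
    payload <- c(payload, paste0("volume_uL=",
                                 format(volume_uL, digits = 15)))
  }
  if (length(payload)) {
    paste(t_ms, kind, paste(payload, collapse = ";"), sep = "\t")
  } else {
    paste(t_ms, kind, sep = "\t")
  }
}

parse_log_line <- function(line, lineno = NA_integer_) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2L || is.na(suppressWarnings(as.integer(parts[1])))) {
    stop("malformed event line ", lineno, ": ", line, call. = FALSE)
  }
  out <- list(t_ms = as.integer(parts[1]), kind = parts[2],
              odor = NA_character_, trial = NA_integer_,
              volume_uL = NA_real_)
  if (length(parts) >= 3L && nzchar(parts[3])) {
    kvs <- strsplit(parts[3], ";", fixed = TRUE)[[1]]
    for (kv in kvs) {
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) stop("malformed payload on line ", lineno, ": ", line,
                       call. = FALSE)
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      out[[key]] <- switch(key,
        odor = val,
        trial = as.integer(val),
        volume_uL = as.numeric(val),
        val)  # unknown payload keys preserved verbatim
    }
  }
  out
}

#' Write a session record to plain-text files
#'
#' Serializes a `session_record` into a line-delimited event log, a trial
#' table (CSV) and a JSON summary carrying the machine-readable provenance
#' header (schema version, configuration snapshot, seed, totals,
#' termination reason). `read_session` reproduces the record losslessly.
#'
#' @param record a `session_record`.
#' @param stem file-path stem; `.events.log`, `.trials.csv` and
#'   `.summary.json` are appended.
#' @return `write_session` returns `stem` invisibly; `read_session` returns
#'   the reconstructed `session_record`.
#' @export
write_session <- function(record, stem) {
  stopifnot(inherits(record, "session_record"))
  ev <- record$events
  lines <- c(
    paste0("# ", LOG_SCHEMA),
    paste0("# phase=", record$phase),
    paste0("# seed=", record$seed),
    vapply(seq_len(nrow(ev)), function(i) {
      serialize_log_line(ev$t_ms[i], ev$kind[i], ev$odor[i], ev$trial[i],
                         ev$volume_uL[i])
    }, character(1))
  )
  writeLines(lines, paste0(stem, ".events.log"))

  tr <- record$trials
  utils::write.csv(tr, paste0(stem, ".trials.csv"), row.names = FALSE,
                   na = "")

  summ <- list(
    schema = record$schema,
    phase = record$phase,
    seed = record$seed,
    config = unclass(record$config),
    totals = record$totals,
    termination_reason = record$termination_reason,
    partial = record$partial
  )
  if (!is.null(record$bouts)) summ$bouts <- record$bouts
  jsonlite::write_json(summ, paste0(stem, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(stem)
}

#' @rdname write_session
#' @param stem file-path stem used when writing.
#' @export
read_session <- function(stem) {
  ev_path <- paste0(stem, ".events.log")
  sm_path <- paste0(stem, ".summary.json")
  tr_path <- paste0(stem, ".trials.csv")
  for (p in c(ev_path, sm_path, tr_path)) {
    if (!file.exists(p)) stop("missing session file: ", p, call. = FALSE)
  }
  lines <- readLines(ev_path)
  if (!length(lines) || lines[1] != paste0("# ", LOG_SCHEMA)) {
    stop("schema-version mismatch in ", ev_path, ": expected '",
         LOG_SCHEMA, "'", call. = FALSE)
  }
  body <- which(!startsWith(lines, "#"))
  parsed <- lapply(body, function(i) parse_log_line(lines[i], i))
  events <- if (length(parsed)) {
    data.frame(
      t_ms = vapply(parsed, `[[`, integer(1), "t_ms"),
      kind = vapply(parsed, `[[`, character(1), "kind"),
      odor = vapply(parsed, `[[`, character(1), "odor"),
      trial = vapply(parsed, `[[`, integer(1), "trial"),
      volume_uL = vapply(parsed, `[[`, numeric(1), "volume_uL"),
      stringsAsFactors = FALSE)
  } else empty_event_log()
  if (nrow(events) == 0L || events$kind[nrow(events)] != "session_end") {
    last_good <- if (length(body)) body[length(body)] else 0L
    stop("event log ", ev_path, " is truncated: no session_end; ",
         "last good line is ", last_good, call. = FALSE)
  }

  summ <- jsonlite::read_json(sm_path, simplifyVector = TRUE)
  if (!identical(summ$schema, LOG_SCHEMA)) {
    stop("schema-version mismatch in ", sm_path, ": found '",
         summ$schema, "', expected '", LOG_SCHEMA, "'", call. = FALSE)
  }
  config <- as_session_config(summ$config)

  trials <- utils::read.csv(
    tr_path, stringsAsFactors = FALSE,
    na.strings = "",
    colClasses = c(index = "integer", paradigm = "character",
                   sample_odor = "character", test_odor = "character",
                   trial_type = "character", delay_s = "numeric",
                   mode = "character", outcome = "character",
                   n_licks = "integer", reward_uL = "numeric"))

  totals <- summ$totals
  totals$n_trials <- as.integer(totals$n_trials)
  totals$n_hits <- as.integer(totals$n_hits)
  totals$reward_uL <- as.numeric(totals$reward_uL)
  if (!is.null(totals$n_bouts)) totals$n_bouts <- as.integer(totals$n_bouts)

  rec <- new_session_record(summ$phase, config, summ$seed, events, trials,
                            totals, summ$termination_reason,
                            partial = isTRUE(summ$partial))
  if (!is.null(summ$bouts)) {
    b <- as.data.frame(summ$bouts, stringsAsFactors = FALSE)
    b$bout <- as.integer(b$bout)
    b$start_ms <- as.integer(b$start_ms)
    b$end_ms <- as.integer(b$end_ms)
    b$n_licks <- as.integer(b$n_licks)
    b$volume_uL <- as.numeric(b$volume_uL)
    rec$bouts <- b
  }
  rec
}

#' Summarize block statistics across sessions
#'
#' Aggregates per-block performance and rates across a group of session
#' records (e.g. one simulated subject per record), reporting mean and
#' standard error of the mean per block with `N` = number of sessions.
#' All records must come from the same paradigm.
#'
#' @param records list of `session_record`s with trial results.
#' @param block_size trials per block; defaults to the records' configured
#'   block size.
#' @return data frame with one row per block: `block`, `n_records`, and
#'   `mean_`/`sem_` columns for performance, hit rate, false-choice rate,
#'   CR rate and d-prime. SEM is 0 for a single record.
#' @export
summarize_sessions <- function(records, block_size = NULL) {
  stopifnot(length(records) >= 1L)
  paradigms <- unique(vapply(records, function(r) r$config$paradigm,
                             character(1)))
  if (length(paradigms) != 1L) {
    stop("cannot summarize mixed paradigms in one group: ",
         paste(paradigms, collapse = ", "), call. = FALSE)
  }
  if (is.null(block_size)) block_size <- records[[1]]$config$block_size
  per <- lapply(records, function(r) {
    block_stats(r$trials$outcome, block_size = block_size)
  })
  n_blocks <- min(vapply(per, nrow, integer(1)))
  metrics <- c("performance", "hit_rate", "false_choice_rate", "cr_rate",
               "d_prime")
  rows <- lapply(seq_len(n_blocks), function(b) {
    row <- list(block = b, n_records = length(records))
    for (m in metrics) {
      vals <- vapply(per, function(p) p[[m]][b], numeric(1))
      row[[paste0("mean_", m)]] <- mean(vals)
      row[[paste0("sem_", m)]] <- if (length(vals) > 1L) {
        stats::sd(vals) / sqrt(length(vals))
      } else 0
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
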