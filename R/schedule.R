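#' Schedule a balanced, pseudo-random trial sequence
#'
#' Trials are scheduled in blocks (default 24) in which every odor-sequence
#' type appears equally often — 4 types for the two-odor tasks (DNMS, DPA),
#' 2 for the single-cue task (GNG) — so that block statistics compare across
#' tasks. Order within each block is an independent seeded shuffle, and each
#' trial's delay is drawn uniformly from the configured delay range on the
#' same seeded stream.
#'
#' @param config a `session_config` (see [default_config()]).
#' @param n_trials positive multiple of `config$block_size` (0 allowed).
#' @param seed optional integer; when supplied the schedule is drawn on a
#'   private RNG stream and the caller's RNG state is untouched.
#' @param map optional `contingency_map`; defaults to the paradigm's map.
#' @return a data frame of trial specifications: `index`, `paradigm`,
#'   `sample_odor`, `test_odor`, `trial_type`, `delay_s`.
#' @examples
#' sched <- schedule_trials(default_config("DNMS"), 24, seed = 1)
#' table(sched$trial_type)  # 12 go, 12 nogo
#' @export
schedule_trials <- function(config, n_trials, seed = NULL, map = NULL) {
  validate_config(config)
  if (!is.null(seed)) {
    return(with_private_rng(seed, schedule_trials(config, n_trials,
                                                  map = map)))
  }
  n_trials <- as.integer(n_trials)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 0L) {
    stop("n_trials must be a non-negative integer", call. = FALSE)
  }
  if (n_trials %% config$block_size != 0L) {
    stop("n_trials (", n_trials, ") must be a multiple of block_size (",
         config$block_size, ")", call. = FALSE)
  }
  if (is.null(map)) map <- contingency_map(config$paradigm)
  if (n_trials == 0L) {
    return(data.frame(index = integer(0), paradigm = character(0),
                      sample_odor = character(0), test_odor = character(0),
                      trial_type = character(0), delay_s = numeric(0),
                      stringsAsFactors = FALSE))
  }
  k <- nrow(map)
  reps <- config$block_size %/% k
  n_blocks <- n_trials %/% config$block_size
  rows <- integer(0)
  for (b in seq_len(n_blocks)) {
    block <- rep(seq_len(k), each = reps)
    rows <- c(rows, sample(block))  # seeded shuffle within block
  }
  delay <- if (is.null(config$delay_range_s)) {
    rep(0, n_trials)
  } else {
    # rounded to the engine's ms resolution
    round(stats::runif(n_trials, config$delay_range_s[1],
                       config$delay_range_s[2]), 3)
  }
  data.frame(
    index = seq_len(n_trials),
    paradigm = config$paradigm,
    sample_odor = map$sample_odor[rows],
    test_odor = map$test_odor[rows],
    trial_type = map$trial_type[rows],
    delay_s = delay,
    stringsAsFactors = FALSE
  )
}

# evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
with_private_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
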