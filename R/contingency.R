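# Stock odorants and the cue roles they play in each task. The same four
# odorants serve all paradigms: DNMS discriminates 1-Butanol vs Methyl
# butyrate, DPA pairs those samples with Hexanoic acid / Octane tests, GNG
# uses Hexanoic acid as Go and Octane as No-go.
default_odors <- function(paradigm) {
  switch(paradigm,
    DNMS = list(samples = c("1-Butanol", "Methyl butyrate"),
                tests   = c("1-Butanol", "Methyl butyrate")),
    DPA  = list(samples = c("1-Butanol", "Methyl butyrate"),
                tests   = c("Hexanoic acid", "Octane")),
    GNG  = list(samples = c("Hexanoic acid", "Octane"), tests = NULL),
    GNG_REV = list(samples = c("Hexanoic acid", "Octane"), tests = NULL),
    stop("unknown paradigm: ", paradigm, call. = FALSE)
  )
}

#' Build the odor-to-outcome contingency map of a paradigm
#'
#' Encodes which odor sequences are rewarded-if-licked ("go") under each
#' task rule: DNMS rewards non-matched sample/test pairs, DPA rewards the
#' designated sample-test pairs (S1-T1, S2-T2), GNG rewards the Go cue, and
#' GNG reversal is the GNG map with go and no-go swapped.
#'
#' @param paradigm one of `"DNMS"`, `"DPA"`, `"GNG"`, `"GNG_REV"`.
#' @param samples,tests optional odor identities; defaults are the stock
#'   odorant panel.
#' @return an object of class `contingency_map`: a data frame with columns
#'   `sample_odor`, `test_odor` (`NA` for single-cue tasks) and
#'   `trial_type` (`"go"`/`"nogo"`), one row per odor-sequence type, plus a
#'   `paradigm` attribute.
#' @examples
#' contingency_map("GNG")
#' @export
contingency_map <- function(paradigm, samples = NULL, tests = NULL) {
  if (!(paradigm %in% PARADIGMS)) {
    stop("unknown paradigm ", paradigm, "; valid options are: ",
         paste(PARADIGMS, collapse = ", "), call. = FALSE)
  }
  odors <- default_odors(paradigm)
  if (!is.null(samples)) odors$samples <- samples
  if (!is.null(tests)) odors$tests <- tests

  if (paradigm %in% c("GNG", "GNG_REV")) {
    stopifnot(length(odors$samples) == 2L)
    map <- data.frame(
      sample_odor = odors$samples,
      test_odor = NA_character_,
      trial_type = c("go", "nogo"),  # first cue is Go
      stringsAsFactors = FALSE
    )
    if (paradigm == "GNG_REV") map$trial_type <- rev(map$trial_type)
  } else {
    grid <- expand.grid(s = seq_along(odors$samples),
                        t = seq_along(odors$tests))
    type <- if (paradigm == "DNMS") {
      ifelse(grid$s == grid$t, "nogo", "go")   # non-matched pairs rewarded
    } else {
      ifelse(grid$s == grid$t, "go", "nogo")   # designated pairs rewarded
    }
    map <- data.frame(
      sample_odor = odors$samples[grid$s],
      test_odor = odors$tests[grid$t],
      trial_type = type,
      stringsAsFactors = FALSE
    )
  }
  attr(map, "paradigm") <- paradigm
  class(map) <- c("contingency_map", "data.frame")
  map
}

#' Reverse a go/no-go contingency
#'
#' Swaps the go/no-go assignment of every cue, modeling the reversal stage
#' in which the odor-reward relationship of a learned GNG task is inverted.
#' Applying the reversal twice restores the original map. Reversal is
#' defined only for the single-cue (GNG) task.
#'
#' @param map a `contingency_map` with paradigm `"GNG"` or `"GNG_REV"`.
#' @return the reversed `contingency_map`.
#' @export
apply_reversal <- function(map) {
  stopifnot(inherits(map, "contingency_map"))
  paradigm <- attr(map, "paradigm")
  if (!(paradigm %in% c("GNG", "GNG_REV"))) {
    stop("reversal is defined only for the GNG task, not ", paradigm,
         call. = FALSE)
  }
  map$trial_type <- ifelse(map$trial_type == "go", "nogo", "go")
  attr(map, "paradigm") <- if (paradigm == "GNG") "GNG_REV" else "GNG"
  map
}

# trial type of one (sample, test) sequence under a map
trial_type_for <- function(map, sample_odor, test_odor = NA_character_) {
  hit <- map$sample_odor == sample_odor &
    (is.na(map$test_odor) == is.na(test_odor)) &
    (is.na(map$test_odor) | map$test_odor %in% test_odor)
  if (sum(hit) != 1L) {
    stop("odor sequence (", sample_odor, ", ", test_odor,
         ") not found in contingency map", call. = FALSE)
  }
  map$trial_type[hit]
}

# key identifying an odor-sequence type, used by learning agents
sequence_key <- function(sample_odor, test_odor = NA_character_) {
  ifelse(is.na(test_odor), sample_odor, paste(sample_odor, test_odor,
                                              sep = " > "))
}
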