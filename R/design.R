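#' Session configuration for the obstacle-crossing attention paradigm
#'
#' Bundles the timing constants and block composition of a testing session.
#' The defaults reproduce the standard protocol: four blocks of 72 trials
#' (48 walking + 24 stationary), a 300 ms cue-test interval, a 77.8 ms Gabor
#' presentation, and a step-onset validity window running from Gabor offset
#' (377.8 ms) to 1000 ms after cue onset.
#'
#' @param n_blocks Number of blocks.
#' @param walking_trials_per_block Walking (obstacle-crossing) trials per
#'   block; must be divisible by 8 (4 locations x 2 cue directions).
#' @param stationary_trials_per_block Stationary trials per block; must be
#'   divisible by 4 (locations).
#' @param cue_test_interval Cue onset to Gabor onset, ms.
#' @param gabor_duration Gabor patch presentation time, ms.
#' @param cross_cue_offset_delay Gabor offset to cross/cue offset, ms.
#' @param step_onset_max Latest valid step onset after cue onset, ms.
#' @param fixation_duration Pre-cue fixation period, ms (used by the gaze
#'   window).
#' @param seed Integer seed for schedule randomisation.
#'
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_blocks = 4L,
                           walking_trials_per_block = 48L,
                           stationary_trials_per_block = 24L,
                           cue_test_interval = 300,
                           gabor_duration = 77.8,
                           cross_cue_offset_delay = 44.4,
                           step_onset_max = 1000,
                           fixation_duration = 500,
                           seed = 1L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    walking_trials_per_block = as.integer(walking_trials_per_block),
    stationary_trials_per_block = as.integer(stationary_trials_per_block),
    cue_test_interval = cue_test_interval,
    gabor_duration = gabor_duration,
    cross_cue_offset_delay = cross_cue_offset_delay,
    step_onset_min = cue_test_interval + gabor_duration,
    step_onset_max = step_onset_max,
    fixation_duration = fixation_duration,
    locations = gabor_locations(),
    seed = as.integer(seed)
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  blocks: %d (%d walking + %d stationary trials each)\n",
              x$n_blocks, x$walking_trials_per_block,
              x$stationary_trials_per_block))
  cat(sprintf("  cue-test interval %g ms, Gabor %g ms, cross offset +%g ms\n",
              x$cue_test_interval, x$gabor_duration, x$cross_cue_offset_delay))
  cat(sprintf("  valid step onset: (%g, %g] ms after cue onset\n",
              x$step_onset_min, x$step_onset_max))
  invisible(x)
}

#' The four potential stepping / Gabor locations
#'
#' R1 and L1 are the right- and left-leg first-step locations, R2 and L2 the
#' second-step locations.
#'
#' @return Character vector `c("R1", "L1", "R2", "L2")`.
#' @export
gabor_locations <- function() c("R1", "L1", "R2", "L2")

validate_session_config <- function(cfg) {
  durs <- c(cfg$cue_test_interval, cfg$gabor_duration,
            cfg$cross_cue_offset_delay, cfg$step_onset_max,
            cfg$fixation_duration)
  if (any(durs <= 0)) {
    stop("all session durations must be positive", call. = FALSE)
  }
  if (cfg$step_onset_max <= cfg$step_onset_min) {
    stop("step_onset_max must exceed Gabor offset (cue_test_interval + gabor_duration)",
         call. = FALSE)
  }
  if (length(cfg$locations) != 4L) {
    stop("exactly 4 Gabor locations are required", call. = FALSE)
  }
  if (cfg$walking_trials_per_block %% 8L != 0L) {
    stop("walking_trials_per_block must be divisible by 8 ",
         "(4 locations x 2 cue directions)", call. = FALSE)
  }
  if (cfg$stationary_trials_per_block %% 4L != 0L) {
    stop("stationary_trials_per_block must be divisible by 4 (locations)",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Map a movement cue and Gabor location to relevance and step
#'
#' The cue dictates the stepping locations: a rightward arrow means the first
#' step lands in R1 and the second in L2, so R1 and L2 are the stepping
#' locations and L1, R2 the non-stepping ones; a leftward arrow mirrors this.
#' The horizontal bar (stationary trials) carries no relevance. Locations R1
#' and L1 belong to the first step, R2 and L2 to the second.
#'
#' @param cue `"right_arrow"`, `"left_arrow"` or `"horizontal_bar"`
#'   (vectorised).
#' @param gabor_location `"R1"`, `"L1"`, `"R2"` or `"L2"` (vectorised).
#'
#' @return A tibble with columns `relevance` (`"stepping"`, `"non_stepping"`,
#'   `"not_applicable"`) and `step` (`"step1"`, `"step2"`).
#' @export
assign_relevance <- function(cue, gabor_location) {
  cue <- as.character(cue)
  loc <- as.character(gabor_location)
  bad_cue <- !cue %in% c("right_arrow", "left_arrow", "horizontal_bar")
  bad_loc <- !loc %in% gabor_locations()
  if (any(bad_cue)) stop("invalid cue: ", cue[bad_cue][1], call. = FALSE)
  if (any(bad_loc)) stop("invalid Gabor location: ", loc[bad_loc][1],
                         call. = FALSE)
  step <- ifelse(loc %in% c("R1", "L1"), "step1", "step2")
  stepping_right <- loc %in% c("R1", "L2")
  relevance <- dplyr::case_when(
    cue == "horizontal_bar" ~ "not_applicable",
    cue == "right_arrow" & stepping_right ~ "stepping",
    cue == "left_arrow" & !stepping_right ~ "stepping",
    TRUE ~ "non_stepping"
  )
  tibble::tibble(relevance = relevance, step = step)
}

#' Generate the full balanced trial schedule for a session
#'
#' Enumerates, per block, 12 walking presentations of the Gabor patch at each
#' location (6 right-cued, 6 left-cued) and 6 stationary presentations per
#' location, balances the tilt side within every (location, cue, condition)
#' cell up to parity, and shuffles each block with the configured seed. Each
#' trial's Gabor orientation is the supplied per-location discrimination
#' threshold.
#'
#' @param config A [session_config()].
#' @param thresholds Named numeric vector of per-location orientation
#'   thresholds in degrees; names must cover `R1, L1, R2, L2`, all values
#'   positive.
#' @param balance_tilt Balance tilt side within cells (default) or draw it
#'   i.i.d. Bernoulli(0.5).
#'
#' @return A tibble of trial specifications with one row per trial: columns
#'   `trial_id`, `block`, `condition`, `cue`, `gabor_location`, `gabor_side`,
#'   `gabor_orientation`, `relevance`, `step`.
#' @export
generate_session <- function(config = session_config(), thresholds,
                             balance_tilt = TRUE) {
  validate_session_config(config)
  locs <- config$locations
  if (is.null(names(thresholds)) || !all(locs %in% names(thresholds))) {
    stop("thresholds must be a named vector covering locations ",
         paste(locs, collapse = ", "), call. = FALSE)
  }
  thresholds <- thresholds[locs]
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop("all per-location thresholds must be positive", call. = FALSE)
  }

  per_cell_walk <- config$walking_trials_per_block / 8L   # per (loc, cue)
  per_cell_stat <- config$stationary_trials_per_block / 4L

  tilt_for <- function(n) {
    if (balance_tilt) {
      sides <- rep(c("right", "left"), length.out = n)
    } else {
      sides <- sample(c("right", "left"), n, replace = TRUE)
    }
    sides
  }

  build_block <- function(block) {
    walk <- tidyr::expand_grid(
      gabor_location = locs,
      cue = c("right_arrow", "left_arrow"),
      rep = seq_len(per_cell_walk)
    )
    walk$condition <- "crossing"
    stat <- tidyr::expand_grid(
      gabor_location = locs,
      cue = "horizontal_bar",
      rep = seq_len(per_cell_stat)
    )
    stat$condition <- "stationary"
    trials <- dplyr::bind_rows(walk, stat)
    # tilt side balanced within each (location, cue, condition) cell
    trials <- dplyr::group_by(trials, .data$gabor_location, .data$cue,
                              .data$condition)
    trials <- dplyr::mutate(trials, gabor_side = tilt_for(dplyr::n()))
    trials <- dplyr::ungroup(trials)
    trials <- trials[sample.int(nrow(trials)), ]
    trials$block <- block
    trials
  }

  schedule <- withr::with_seed(config$seed, {
    dplyr::bind_rows(lapply(seq_len(config$n_blocks), build_block))
  })
  schedule$rep <- NULL
  schedule$trial_id <- seq_len(nrow(schedule))
  schedule$gabor_orientation <- unname(thresholds[schedule$gabor_location])
  rel <- assign_relevance(schedule$cue, schedule$gabor_location)
  schedule$relevance <- rel$relevance
  schedule$step <- rel$step
  schedule[, c("trial_id", "block", "condition", "cue", "gabor_location",
               "gabor_side", "gabor_orientation", "relevance", "step")]
}

#' Write / read a session configuration as YAML
#'
#' @param config A [session_config()].
#' @param path File path.
#' @return `read_session_config()` returns a `session_config`;
#'   `write_session_config()` its path, invisibly.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  fields <- config[c("n_blocks", "walking_trials_per_block",
                     "stationary_trials_per_block", "cue_test_interval",
                     "gabor_duration", "cross_cue_offset_delay",
                     "step_onset_max", "fixation_duration", "seed")]
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  do.call(session_config, yaml::read_yaml(path))
}

#' Write / read per-location thresholds as JSON
#'
#' @param thresholds Named numeric vector, degrees (names `R1, L1, R2, L2`).
#' @param path File path.
#' @return `read_thresholds()` returns the named numeric vector;
#'   `write_thresholds()` its path, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(as.list(thresholds), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  unlist(jsonlite::read_json(path))
}

#' Write / read a trial schedule as CSV
#'
#' @param schedule Tibble from [generate_session()].
#' @param path File path.
#' @return `read_schedule()` returns the schedule tibble; `write_schedule()`
#'   its path, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
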