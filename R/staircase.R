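#' Create a fresh 3-down/1-up staircase track
#'
#' Transformed up-down staircase for orientation-discrimination thresholds:
#' three consecutive correct responses lower the Gabor tilt by one step
#' (harder), any error raises it (easier). The procedure targets the level at
#' which the probability of a correct response is 0.794 (the 3-down/1-up
#' fixed point, conventionally reported as the 79% threshold). A track
#' terminates after the sixth reversal of adjustment direction, and the
#' threshold is the mean of the last four reversal levels.
#'
#' Levels are floored one step above zero; a down-adjustment at the floor
#' holds the level but still counts as a downward adjustment, so a perfect
#' responder bouncing on the floor still accrues reversals on later errors.
#'
#' @param start_level Starting tilt from vertical, degrees.
#' @param step_size Staircase step, degrees.
#' @param n_down Correct responses required before a down step.
#' @param n_reversals Reversals at which the track terminates.
#' @param floor Minimum level, degrees; defaults to one step size.
#'
#' @return A list of class `staircase_state`.
#' @export
new_staircase <- function(start_level = 6, step_size = 0.3, n_down = 3L,
                          n_reversals = 6L, floor = step_size) {
  stopifnot(start_level > 0, step_size > 0, floor > 0, n_down >= 1,
            n_reversals >= 2)
  structure(list(
    current_level = start_level,
    step_size = step_size,
    n_down = as.integer(n_down),
    n_reversals = as.integer(n_reversals),
    floor = floor,
    consecutive_correct = 0L,
    reversal_levels = numeric(0),
    last_direction = "none",
    terminated = FALSE,
    n_trials = 0L,
    levels = numeric(0),    # level presented on each trial
    responses = logical(0)
  ), class = "staircase_state")
}

#' Feed one response to a staircase track
#'
#' Applies the 3-down/1-up rule: after `n_down` consecutive correct responses
#' the level drops one step (and the counter resets); after any incorrect
#' response the level rises one step (counter resets). A reversal is logged
#' whenever the adjustment direction flips relative to the previous
#' adjustment, at the level being adjusted away from; the track terminates
#' once the configured number of reversals is reached.
#'
#' @param state A `staircase_state`.
#' @param correct Logical; was the response correct?
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  if (state$terminated) {
    stop("staircase track already terminated", call. = FALSE)
  }
  state$n_trials <- state$n_trials + 1L
  state$levels <- c(state$levels, state$current_level)
  state$responses <- c(state$responses, correct)

  direction <- NULL
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= state$n_down) {
      direction <- "down"
      state$consecutive_correct <- 0L
    }
  } else {
    direction <- "up"
    state$consecutive_correct <- 0L
  }

  if (!is.null(direction)) {
    if (state$last_direction != "none" && direction != state$last_direction) {
      state$reversal_levels <- c(state$reversal_levels, state$current_level)
      if (length(state$reversal_levels) >= state$n_reversals) {
        state$terminated <- TRUE
      }
    }
    if (direction == "down") {
      # held at the floor this still counts as a downward adjustment
      state$current_level <- max(state$floor,
                                 state$current_level - state$step_size)
    } else {
      state$current_level <- state$current_level + state$step_size
    }
    state$last_direction <- direction
  }
  state
}

#' Threshold estimate from a terminated staircase track
#'
#' @param state A terminated `staircase_state`.
#' @return Mean of the last four reversal levels, degrees.
#' @export
staircase_threshold <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  if (!state$terminated) {
    stop("staircase not terminated: ", length(state$reversal_levels),
         " of ", state$n_reversals, " reversals logged", call. = FALSE)
  }
  mean(utils::tail(state$reversal_levels, 4L))
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("<staircase_state> level %.2f deg, %d trials, %d reversals%s\n",
              x$current_level, x$n_trials, length(x$reversal_levels),
              if (x$terminated) " (terminated)" else ""))
  invisible(x)
}

#' Run interleaved staircases at the four walkway locations
#'
#' Runs one 3-down/1-up track per location simultaneously: each trial draws
#' uniformly among the unterminated tracks, randomises the cue direction and
#' tilt side (neither influences the simulated response), presents the
#' track's current level and feeds the response back. Stops when every track
#' has terminated or the trial cap is reached.
#'
#' @param p_correct_fn Function `(location, orientation_deg) -> probability`
#'   of a correct discrimination; typically the psychometric function of an
#'   [observer_model()] via [observer_p_correct()].
#' @param locations Character vector of track labels.
#' @param seed Integer seed.
#' @param max_trials Cap on total trials across tracks; exceeding it emits a
#'   warning and returns the partial result.
#' @inheritParams new_staircase
#'
#' @return A list with `results` (tibble: location, threshold, n_trials,
#'   n_reversals, terminated), `trace` (tibble: trial, location, level, cue,
#'   gabor_side, correct, reversal) and `states` (final `staircase_state`s).
#'   Unterminated tracks get an `NA` threshold.
#' @export
run_interleaved_thresholding <- function(p_correct_fn,
                                         locations = gabor_locations(),
                                         seed = 1L,
                                         start_level = 6,
                                         step_size = 0.3,
                                         n_down = 3L,
                                         n_reversals = 6L,
                                         max_trials = 2000L) {
  stopifnot(is.function(p_correct_fn), length(locations) >= 1)
  states <- stats::setNames(
    lapply(locations, function(l) {
      new_staircase(start_level, step_size, n_down, n_reversals)
    }),
    locations
  )
  tr_loc <- character(max_trials)
  tr_level <- numeric(max_trials)
  tr_cue <- character(max_trials)
  tr_side <- character(max_trials)
  tr_correct <- logical(max_trials)
  tr_reversal <- logical(max_trials)
  trial <- 0L
  withr::with_seed(seed, {
    while (trial < max_trials) {
      open <- names(states)[!vapply(states, `[[`, TRUE, "terminated")]
      if (length(open) == 0L) break
      trial <- trial + 1L
      loc <- if (length(open) == 1L) open else sample(open, 1L)
      st <- states[[loc]]
      level <- st$current_level
      p <- p_correct_fn(loc, level)
      u <- stats::runif(3)
      correct <- u[1] < p
      n_rev_before <- length(st$reversal_levels)
      states[[loc]] <- staircase_update(st, correct)
      tr_loc[trial] <- loc
      tr_level[trial] <- level
      tr_cue[trial] <- if (u[2] < 0.5) "right_arrow" else "left_arrow"
      tr_side[trial] <- if (u[3] < 0.5) "right" else "left"
      tr_correct[trial] <- correct
      tr_reversal[trial] <- length(states[[loc]]$reversal_levels) > n_rev_before
    }
  })
  keep <- seq_len(trial)
  trace <- tibble::tibble(
    trial = keep, location = tr_loc[keep], level = tr_level[keep],
    cue = tr_cue[keep], gabor_side = tr_side[keep],
    correct = tr_correct[keep], reversal = tr_reversal[keep]
  )
  open <- names(states)[!vapply(states, `[[`, TRUE, "terminated")]
  if (length(open) > 0L) {
    warning("trial cap (", max_trials, ") reached before tracks terminated: ",
            paste(open, collapse = ", "), call. = FALSE)
  }
  results <- dplyr::bind_rows(lapply(locations, function(l) {
    st <- states[[l]]
    tibble::tibble(
      location = l,
      threshold = if (st$terminated) staircase_threshold(st) else NA_real_,
      n_trials = st$n_trials,
      n_reversals = length(st$reversal_levels),
      terminated = st$terminated
    )
  }))
  list(results = results, trace = trace, states = states)
}

#' Percent-correct fixed point of the n-down/1-up rule
#'
#' The transformed up-down staircase equilibrates where the probability of
#' `n_down` consecutive correct responses equals 1/2, i.e. at
#' `p = 0.5^(1/n_down)`; 0.794 for the 3-down/1-up rule.
#'
#' @param n_down Correct responses required per down step.
#' @return Probability of a correct response at convergence.
#' @export
staircase_fixed_point <- function(n_down = 3L) 0.5^(1 / n_down)
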