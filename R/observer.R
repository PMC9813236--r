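#' Simulated observer for the orientation-discrimination task
#'
#' An observer couples two descriptions of discrimination behaviour, used by
#' different stages of the pipeline:
#'
#' * a per-location cumulative-Gaussian psychometric function over
#'   orientation magnitude (with a lapse rate), used by the staircase module;
#' * per-cell response probabilities for the experimental session, where a
#'   stationary baseline probability per location is reduced by an attention
#'   deficit at the cells named in `modulation_map` during crossing trials.
#'
#' The psychometric function is parameterised by the orientation at which it
#' crosses the 3-down/1-up convergence probability 0.794 (`threshold79`), so
#' that staircase recovery can be checked against a known truth. Defaults
#' place the four thresholds at the group values observed with this paradigm
#' (L1 4.3, R1 4.0, L2 3.6, R2 3.2 degrees), stationary performance at 90%
#' correct, and a 7.3 percentage-point deficit at the first stepping
#' location.
#'
#' @param threshold79 Named numeric, degrees: per-location orientation at
#'   which the observer is 79.4% correct.
#' @param slope Cumulative-Gaussian SD, degrees.
#' @param lapse Lapse rate in \[0, 0.05\]: probability of a stimulus-independent
#'   random response.
#' @param baseline_p Named (or scalar) stationary probability correct per
#'   location.
#' @param attention_delta Percentage points subtracted from `baseline_p` at
#'   modulated cells on crossing trials; must be >= 0.
#' @param modulation_map Data frame with columns `relevance` and `step`
#'   naming the crossing cells the deficit applies to.
#' @param response_bias Log-odds shift toward reporting "right".
#'
#' @return A list of class `observer_model`.
#' @export
observer_model <- function(threshold79 = c(R1 = 4.0, L1 = 4.3, R2 = 3.2, L2 = 3.6),
                           slope = 1.5,
                           lapse = 0.02,
                           baseline_p = 0.90,
                           attention_delta = 7.3,
                           modulation_map = data.frame(relevance = "stepping",
                                                       step = "step1"),
                           response_bias = 0) {
  locs <- gabor_locations()
  if (is.null(names(threshold79))) names(threshold79) <- locs
  stopifnot(all(locs %in% names(threshold79)), all(threshold79 > 0),
            slope > 0, lapse >= 0, lapse <= 0.05, attention_delta >= 0)
  if (length(baseline_p) == 1L) {
    baseline_p <- stats::setNames(rep(baseline_p, 4L), locs)
  }
  stopifnot(all(locs %in% names(baseline_p)),
            all(baseline_p > 0), all(baseline_p <= 1))
  obs <- list(
    threshold79 = threshold79[locs],
    slope = slope,
    lapse = lapse,
    baseline_p = baseline_p[locs],
    attention_delta = attention_delta,
    modulation_map = modulation_map,
    response_bias = response_bias
  )
  class(obs) <- "observer_model"
  obs
}

#' @export
print.observer_model <- function(x, ...) {
  cat("<observer_model>\n")
  cat("  79.4% thresholds (deg):",
      paste(sprintf("%s=%.2f", names(x$threshold79), x$threshold79),
            collapse = ", "), "\n")
  cat(sprintf("  slope %.2f deg, lapse %.3f, baseline p %.2f-%.2f\n",
              x$slope, x$lapse, min(x$baseline_p), max(x$baseline_p)))
  cat(sprintf("  attention deficit %.1f points at %s\n", x$attention_delta,
              paste(x$modulation_map$relevance, x$modulation_map$step,
                    sep = "/", collapse = ", ")))
  invisible(x)
}

#' Psychometric probability of a correct discrimination
#'
#' `p(x) = 0.5 + (0.5 - lapse) * pnorm((x - mu) / slope)` with `mu` placed so
#' that `p(threshold79) = 0.5^(1/3)`. Vectorised over `orientation`.
#'
#' @param observer An [observer_model()].
#' @param location One of `R1, L1, R2, L2`.
#' @param orientation Orientation magnitude, degrees.
#' @return Probability of a correct response.
#' @export
observer_p_correct <- function(observer, location, orientation) {
  stopifnot(inherits(observer, "observer_model"),
            location %in% names(observer$threshold79))
  target <- staircase_fixed_point(3L)
  # inner-function value needed at threshold79 to hit the 79.4% fixed point
  f_at_thr <- (target - 0.5) / (0.5 - observer$lapse)
  if (f_at_thr >= 1) {
    stop("lapse rate too high for the 79.4% point to be attainable",
         call. = FALSE)
  }
  mu <- observer$threshold79[[location]] - observer$slope * stats::qnorm(f_at_thr)
  0.5 + (0.5 - observer$lapse) * stats::pnorm((orientation - mu) / observer$slope)
}

#' Per-cell response probability during the experimental session
#'
#' Stationary trials use the location's baseline probability; crossing trials
#' subtract the attention deficit at cells named in the observer's
#' modulation map. `shift` adds participant-level effects (in probability
#' units) before clamping to (0.005, 0.995). Vectorised.
#'
#' @param observer An [observer_model()].
#' @param condition `"crossing"` or `"stationary"`.
#' @param relevance `"stepping"`, `"non_stepping"` or `"not_applicable"`.
#' @param step `"step1"` or `"step2"`.
#' @param gabor_location Location label.
#' @param shift Additive probability shift (participant intercepts).
#' @return Probability correct per trial.
#' @export
observer_cell_p <- function(observer, condition, relevance, step,
                            gabor_location, shift = 0) {
  stopifnot(inherits(observer, "observer_model"))
  p <- unname(observer$baseline_p[gabor_location])
  map <- observer$modulation_map
  key <- paste(relevance, step)
  modulated <- condition == "crossing" & key %in% paste(map$relevance, map$step)
  p <- p - (observer$attention_delta / 100) * modulated + shift
  pmin(pmax(p, 0.005), 1)
}

#' Gait generator parameters
#'
#' Defaults reproduce the group obstacle-crossing statistics this paradigm
#' yields: step onset 741 (SD 105) ms truncated to the (377.8, 1000\] ms
#' validity window, lead/trail horizontal distances 84.0 (10.8) / 27.6 (7.5)
#' cm, lead/trail clearances 10.0 (5.4) / 11.3 (6.1) cm, and within-
#' participant foot-placement scatter whose mean planar distance from the
#' Gabor location is 6.0 cm (step 1) and 7.1 cm (step 2) — for isotropic
#' 2-D Gaussian scatter the mean distance is `sd * sqrt(pi/2)`. Violation
#' rates inject too-fast / too-slow onsets at the observed field rates.
#'
#' @param step_onset_mean,step_onset_sd Step-onset distribution, ms.
#' @param lead_hd_mean,lead_hd_sd Lead horizontal distance, cm.
#' @param trail_hd_mean,trail_hd_sd Trail horizontal distance, cm.
#' @param lead_clear_mean,lead_clear_sd Lead clearance, cm.
#' @param trail_clear_mean,trail_clear_sd Trail clearance, cm.
#' @param placement_sd_step1,placement_sd_step2 Per-axis scatter of foot
#'   placement around the Gabor location, cm.
#' @param sampling_rate Kinematic sampling rate, Hz.
#' @param too_fast_rate,too_slow_rate Proportions of trials with onsets
#'   injected outside the validity window.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(step_onset_mean = 741, step_onset_sd = 105,
                        lead_hd_mean = 84.0, lead_hd_sd = 10.8,
                        trail_hd_mean = 27.6, trail_hd_sd = 7.5,
                        lead_clear_mean = 10.0, lead_clear_sd = 5.4,
                        trail_clear_mean = 11.3, trail_clear_sd = 6.1,
                        placement_sd_step1 = 6.0 / sqrt(pi / 2),
                        placement_sd_step2 = 7.1 / sqrt(pi / 2),
                        sampling_rate = 100,
                        too_fast_rate = 0.0007, too_slow_rate = 0.0059) {
  sds <- c(step_onset_sd, lead_hd_sd, trail_hd_sd, lead_clear_sd,
           trail_clear_sd, placement_sd_step1, placement_sd_step2)
  stopifnot(all(sds >= 0), sampling_rate > 0,
            too_fast_rate >= 0, too_slow_rate >= 0,
            too_fast_rate + too_slow_rate < 1)
  structure(as.list(environment()), class = "gait_params")
}

#' Gaze generator parameters
#'
#' Fixational noise around the cross plus rare injected fixation violations
#' exceeding the 2 degree compliance bound. The default violation rate of
#' 0.001 reproduces the ~0.1% gaze-exclusion rate seen with this paradigm.
#'
#' @param noise_sd Fixational/tracker noise SD per plane, degrees.
#' @param violation_rate Probability a trial contains an excursion > 2 deg.
#' @param violation_excursion Magnitude of injected excursions, degrees
#'   (must exceed 2).
#' @param sampling_rate Gaze sampling rate, Hz.
#' @return A list of class `gaze_params`.
#' @export
gaze_params <- function(noise_sd = 0.3, violation_rate = 0.001,
                        violation_excursion = 3.5, sampling_rate = 120) {
  stopifnot(noise_sd >= 0, violation_rate >= 0, violation_rate <= 1,
            violation_excursion > 2, sampling_rate > 0)
  structure(as.list(environment()), class = "gaze_params")
}

#' Obstacle and walkway geometry
#'
#' The obstacle (5 cm high) sits two steps from the start position; first
#' and second mean step locations follow from the default lead/trail
#' horizontal distances.
#'
#' @param distance Start position to obstacle front edge, cm.
#' @param height Obstacle height, cm.
#' @param step1_x,step2_x Mean forward position of the first and second step
#'   landings, cm.
#' @param lateral_offset Lateral distance of each foot from the midline, cm.
#' @return A list of class `obstacle_spec`.
#' @export
obstacle_spec <- function(distance = 112, height = 5,
                          step1_x = distance - 84.0,
                          step2_x = distance - 27.6,
                          lateral_offset = 10) {
  stopifnot(distance > 0, height > 0, step1_x > 0, step2_x > step1_x,
            step2_x < distance)
  structure(list(distance = distance, height = height, step1_x = step1_x,
                 step2_x = step2_x, lateral_offset = lateral_offset),
            class = "obstacle_spec")
}
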