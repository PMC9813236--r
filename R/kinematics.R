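#' Detect step onset from a foot-marker trajectory
#'
#' Step onset is the first sample at which the foot marker has deviated at
#' least 0.5 cm forward (x) or upward (z) from its position at cue onset.
#' Returns `NA` if the threshold is never reached (e.g. stationary trials).
#'
#' @param traj Trajectory tibble with `t_ms`, `x_cm`, `z_cm` (time strictly
#'   increasing, relative to cue onset).
#' @param cue_time Cue onset time, ms, within the trajectory's span.
#' @param threshold_cm Deviation threshold (>= comparison).
#' @return Onset time in ms, or `NA_real_`.
#' @export
detect_step_onset <- function(traj, cue_time = 0, threshold_cm = 0.5) {
  stopifnot(!is.unsorted(traj$t_ms, strictly = TRUE))
  if (cue_time < traj$t_ms[1] || cue_time > traj$t_ms[length(traj$t_ms)]) {
    stop("trajectory does not cover cue_time", call. = FALSE)
  }
  at_cue <- which(traj$t_ms >= cue_time)[1]
  x0 <- traj$x_cm[at_cue]
  z0 <- traj$z_cm[at_cue]
  after <- traj[traj$t_ms >= cue_time, ]
  hit <- which(after$x_cm - x0 >= threshold_cm |
                 after$z_cm - z0 >= threshold_cm)
  if (length(hit) == 0L) return(NA_real_)
  after$t_ms[hit[1]] - cue_time
}

#' Classify a step onset against the validity window
#'
#' Valid onsets fall after the Gabor patch offset (377.8 ms) and at or
#' before 1000 ms following cue onset; earlier onsets are `too_fast`, later
#' ones `too_slow`, and `NA` means no onset was detected.
#'
#' @param onset_ms Detected onset, ms after cue onset (`NA` allowed).
#' @param min_ms Exclusive lower bound (Gabor offset).
#' @param max_ms Inclusive upper bound.
#' @return One of `"valid"`, `"too_fast"`, `"too_slow"`, `"no_onset"`
#'   (vectorised).
#' @export
classify_trial_timing <- function(onset_ms, min_ms = 377.8, max_ms = 1000) {
  dplyr::case_when(
    is.na(onset_ms) ~ "no_onset",
    onset_ms <= min_ms ~ "too_fast",
    onset_ms > max_ms ~ "too_slow",
    TRUE ~ "valid"
  )
}

# Maximal contiguous intervals where the foot is at rest: planar speed below
# `speed_max` (cm/s) and z within `z_tol` of the interval's minimum.
find_stances <- function(traj, speed_max = 2, z_tol = 1, min_samples = 5L) {
  n <- nrow(traj)
  if (n < 2L) return(list())
  dt_s <- diff(traj$t_ms) / 1000
  speed <- c(Inf, sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2) / dt_s)
  slow <- speed < speed_max
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_samples)
  out <- list()
  for (k in keep) {
    idx <- starts[k]:ends[k]
    z <- traj$z_cm[idx]
    ok <- z <= min(z) + z_tol
    if (!all(ok)) idx <- idx[ok]
    if (length(idx) >= min_samples) out[[length(out) + 1L]] <- idx
  }
  out
}

# Temporal midpoint sample of a stance index set.
midstance_index <- function(idx) idx[ceiling(length(idx) / 2)]

#' Obstacle-crossing metrics for a lead/trail trajectory pair
#'
#' Locates the instant each foot's forward position crosses the obstacle's
#' front edge (linear interpolation between the straddling samples), takes
#' the clearance as the interpolated height above the obstacle top at that
#' instant, and the horizontal distance as the obstacle front edge minus the
#' midstance forward position of the stance preceding the crossing. Negative
#' clearance flags obstacle contact.
#'
#' @param lead,trail Trajectory tibbles (`t_ms`, `x_cm`, `y_cm`, `z_cm`).
#' @param obstacle An [obstacle_spec()].
#' @return List of class `gait_metrics`: `lead_horizontal_distance`,
#'   `trail_horizontal_distance`, `lead_clearance`, `trail_clearance`,
#'   `contact` flag.
#' @export
compute_crossing_metrics <- function(lead, trail, obstacle = obstacle_spec()) {
  one <- function(traj, label) {
    xs <- traj$x_cm
    beyond <- which(xs > obstacle$distance)
    if (length(beyond) == 0L) {
      stop(label, " trajectory never crosses the obstacle plane",
           call. = FALSE)
    }
    j <- beyond[1]
    if (j == 1L) stop(label, " trajectory starts beyond the obstacle",
                      call. = FALSE)
    # interpolate the crossing instant on the forward axis
    w <- (obstacle$distance - xs[j - 1]) / (xs[j] - xs[j - 1])
    z_cross <- traj$z_cm[j - 1] + w * (traj$z_cm[j] - traj$z_cm[j - 1])
    t_cross <- traj$t_ms[j - 1] + w * (traj$t_ms[j] - traj$t_ms[j - 1])
    stances <- find_stances(traj)
    stances <- Filter(function(idx) traj$t_ms[midstance_index(idx)] < t_cross &&
                        xs[midstance_index(idx)] < obstacle$distance, stances)
    if (length(stances) == 0L) {
      stop("no stance preceding the crossing found for the ", label,
           " limb", call. = FALSE)
    }
    last_stance <- stances[[length(stances)]]
    x_stance <- xs[midstance_index(last_stance)]
    list(hd = obstacle$distance - x_stance,
         clearance = z_cross - obstacle$height)
  }
  l <- one(lead, "lead")
  t <- one(trail, "trail")
  structure(list(
    lead_horizontal_distance = l$hd,
    trail_horizontal_distance = t$hd,
    lead_clearance = l$clearance,
    trail_clearance = t$clearance,
    contact = l$clearance < 0 || t$clearance < 0
  ), class = "gait_metrics")
}

#' Foot placement relative to the Gabor location
#'
#' Planar Euclidean distance between the foot position at midstance (the
#' temporal midpoint of the first stance after movement onset within the
#' requested span) and the Gabor patch centre on the walkway.
#'
#' @param traj Trajectory tibble (`t_ms`, `x_cm`, `y_cm`, `z_cm`).
#' @param gabor_xy Numeric `c(x, y)` of the Gabor centre, cm.
#' @param after_ms Only stances whose midpoint falls at or after this time
#'   are considered (use the step-onset time to skip the starting posture).
#' @return Distance in cm.
#' @export
compute_foot_placement <- function(traj, gabor_xy, after_ms = 0) {
  stances <- find_stances(traj)
  stances <- Filter(function(idx) traj$t_ms[midstance_index(idx)] >= after_ms,
                    stances)
  if (length(stances) == 0L) {
    stop("no stance detected after ", after_ms, " ms", call. = FALSE)
  }
  mid <- midstance_index(stances[[1]])
  sqrt((traj$x_cm[mid] - gabor_xy[1])^2 + (traj$y_cm[mid] - gabor_xy[2])^2)
}

#' Kinematic metrics table for a cohort
#'
#' Runs onset detection, timing classification, crossing metrics and foot
#' placement over every crossing trial in a long kinematic table.
#'
#' @param kin_long Long tibble with `participant`, `trial_id`, `limb`
#'   (`"lead"`/`"trail"`), `t_ms`, `x_cm`, `y_cm`, `z_cm`.
#' @param obstacle An [obstacle_spec()].
#' @param gabor_steps Optional tibble keyed by `participant` and `trial_id`
#'   with Gabor walkway positions `gabor_step1_x`, `gabor_step1_y`,
#'   `gabor_step2_x`, `gabor_step2_y` (as in a cohort's `kin_truth`); when
#'   present, foot placement per step is computed as the midstance vector
#'   distance from the Gabor centre.
#' @return Tibble with one row per trial: onset, timing status, horizontal
#'   distances, clearances, contact flag, foot placements.
#' @export
gait_metrics_report <- function(kin_long, obstacle = obstacle_spec(),
                                gabor_steps = NULL) {
  keys <- dplyr::distinct(kin_long, .data$participant, .data$trial_id)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    tr <- kin_long[kin_long$participant == keys$participant[i] &
                     kin_long$trial_id == keys$trial_id[i], ]
    lead <- tr[tr$limb == "lead", ]
    trail <- tr[tr$limb == "trail", ]
    onset <- detect_step_onset(lead)
    status <- classify_trial_timing(onset)
    met <- tryCatch(compute_crossing_metrics(lead, trail, obstacle),
                    error = function(e) NULL)
    fp1 <- fp2 <- NA_real_
    if (!is.null(gabor_steps) && !is.na(onset)) {
      gs <- gabor_steps[gabor_steps$participant == keys$participant[i] &
                          gabor_steps$trial_id == keys$trial_id[i], ]
      if (nrow(gs) == 1L) {
        fp1 <- tryCatch(
          compute_foot_placement(lead, c(gs$gabor_step1_x, gs$gabor_step1_y),
                                 after_ms = onset),
          error = function(e) NA_real_)
        fp2 <- tryCatch(
          compute_foot_placement(trail, c(gs$gabor_step2_x, gs$gabor_step2_y),
                                 after_ms = onset),
          error = function(e) NA_real_)
      }
    }
    tibble::tibble(
      participant = keys$participant[i], trial_id = keys$trial_id[i],
      step_onset = onset, timing_status = status,
      lead_horizontal_distance = if (is.null(met)) NA_real_ else
        met$lead_horizontal_distance,
      trail_horizontal_distance = if (is.null(met)) NA_real_ else
        met$trail_horizontal_distance,
      lead_clearance = if (is.null(met)) NA_real_ else met$lead_clearance,
      trail_clearance = if (is.null(met)) NA_real_ else met$trail_clearance,
      contact = if (is.null(met)) NA else met$contact,
      foot_placement_step1 = fp1, foot_placement_step2 = fp2
    )
  })
  dplyr::bind_rows(rows)
}
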