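# Synthetic cohort generation: responses, gaze traces, foot trajectories.
# Every simulated quantity is also emitted in a ground-truth ledger so
# downstream detectors and estimators can be tested by recovery.

# Truncated-normal draws by inverse-CDF.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Simulate one verbal discrimination response
#'
#' Draws a Bernoulli response with the observer's cell probability after
#' attention modulation, then converts it to a reported tilt side; a nonzero
#' response bias shifts the log-odds of reporting "right".
#'
#' @param observer An [observer_model()].
#' @param trial A one-row trial spec (list or data frame row) with fields
#'   `condition`, `relevance`, `step`, `gabor_location`, `gabor_side`,
#'   `gabor_orientation`.
#' @param shift Additive probability shift (participant intercepts).
#' @return List with `reported_side` and `correct`.
#' @export
simulate_response <- function(observer, trial, shift = 0) {
  stopifnot(trial$gabor_orientation > 0)
  out <- simulate_responses(observer, tibble::as_tibble(trial[
    c("condition", "relevance", "step", "gabor_location", "gabor_side",
      "gabor_orientation")]), shift = shift)
  list(reported_side = out$reported_side, correct = out$correct)
}

#' Simulate responses for a whole schedule (vectorised)
#'
#' @param observer An [observer_model()].
#' @param schedule Trial schedule from [generate_session()].
#' @param shift Additive probability shift, scalar or per-trial.
#' @return The schedule with `p_correct_true`, `reported_side` and `correct`
#'   columns appended.
#' @export
simulate_responses <- function(observer, schedule, shift = 0) {
  p <- observer_cell_p(observer, schedule$condition, schedule$relevance,
                       schedule$step, schedule$gabor_location, shift)
  p_right <- ifelse(schedule$gabor_side == "right", p, 1 - p)
  if (observer$response_bias != 0) {
    p_right <- stats::plogis(stats::qlogis(p_right) + observer$response_bias)
  }
  report_right <- stats::runif(nrow(schedule)) < p_right
  schedule$p_correct_true <- p
  schedule$reported_side <- ifelse(report_right, "right", "left")
  schedule$correct <- schedule$reported_side == schedule$gabor_side
  schedule
}

#' Simulate a fixational gaze trace for one trial
#'
#' Zero-mean Gaussian angular noise around the fixation cross over the
#' fixation-to-cross-offset window, sampled at the tracker rate. With
#' probability `violation_rate` (or when `violation = TRUE`) a brief
#' saccade-like excursion exceeding the 2 degree compliance bound is
#' injected after the reference period and flagged in the returned truth.
#'
#' @param gaze A [gaze_params()].
#' @param config A [session_config()] (sets the window).
#' @param violation Force (TRUE/FALSE) or draw (NULL) a violation.
#' @return List with `trace` (tibble `t_ms`, `azimuth_deg`,
#'   `elevation_deg`), `violation` flag and `window` (start/end ms relative
#'   to cue onset).
#' @export
simulate_gaze <- function(gaze = gaze_params(), config = session_config(),
                          violation = NULL) {
  dt <- 1000 / gaze$sampling_rate
  t_start <- -config$fixation_duration
  t_end <- config$cue_test_interval + config$gabor_duration +
    config$cross_cue_offset_delay
  t_ms <- seq(t_start, t_end, by = dt)
  n <- length(t_ms)
  az <- stats::rnorm(n, 0, gaze$noise_sd)
  el <- stats::rnorm(n, 0, gaze$noise_sd)
  if (is.null(violation)) violation <- stats::runif(1) < gaze$violation_rate
  if (violation) {
    eligible <- which(t_ms >= t_start + 150)
    at <- sample(eligible, 1L)
    pulse <- at:min(n, at + 7L)
    ang <- stats::runif(1, 0, 2 * pi)
    az[pulse] <- az[pulse] + gaze$violation_excursion * cos(ang)
    el[pulse] <- el[pulse] + gaze$violation_excursion * sin(ang)
  }
  list(trace = tibble::tibble(t_ms = t_ms, azimuth_deg = az,
                              elevation_deg = el),
       violation = violation,
       window = c(start = t_start, end = t_end))
}

# Raised-cosine interpolation profile on [0, 1].
rc_profile <- function(s) (1 - cos(pi * pmin(pmax(s, 0), 1))) / 2

# z as a function of x over an obstacle-crossing swing: half-sine rise to
# the apex exactly above the obstacle front edge, half-cosine descent.
crossing_z <- function(x, x_from, x_cross, x_land, apex) {
  z <- ifelse(
    x <= x_cross,
    apex * sin((pi / 2) * (x - x_from) / (x_cross - x_from)),
    apex * cos((pi / 2) * (x - x_cross) / (x_land - x_cross))
  )
  pmax(z, 0)
}

#' Simulate lead and trail foot-marker trajectories for one trial
#'
#' Crossing trials embed, on the kinematic sampling grid: a step-onset time
#' (the first sample at which the cued foot has deviated >= 0.5 cm forward
#' from its cue-onset position — movement begins one sample earlier so the
#' threshold is reached exactly at the embedded onset); first- and
#' second-step landings scattered around the Gabor locations; and
#' obstacle-crossing swings whose apex lies exactly above the obstacle's
#' front edge at the drawn clearance. Pre-movement samples carry
#' sub-threshold jitter (< 0.5 cm by construction). Stationary trials return
#' flat traces with no embedded onset.
#'
#' All draws can be overridden through `truth_in` for construction tests.
#'
#' @param gait A [gait_params()].
#' @param obstacle An [obstacle_spec()].
#' @param condition `"crossing"` or `"stationary"`.
#' @param gabor_step1,gabor_step2 Numeric `c(x, y)` walkway positions (cm) of
#'   the Gabor / intended landing for steps 1 and 2.
#' @param truth_in Optional named list overriding any of `onset_ms`,
#'   `timing_status`, `step1_x`, `step1_y`, `step2_x`, `step2_y`,
#'   `lead_clearance`, `trail_clearance`.
#' @return List with `lead` and `trail` trajectory tibbles (`t_ms`, `x_cm`,
#'   `y_cm`, `z_cm`) and `truth` (embedded onset, timing status, horizontal
#'   distances, clearances, placements).
#' @export
simulate_foot_trajectories <- function(gait = gait_params(),
                                       obstacle = obstacle_spec(),
                                       condition = "crossing",
                                       gabor_step1 = c(obstacle$step1_x,
                                                       obstacle$lateral_offset),
                                       gabor_step2 = c(obstacle$step2_x,
                                                       -obstacle$lateral_offset),
                                       truth_in = list()) {
  dt <- 1000 / gait$sampling_rate
  jitter <- function(n) pmin(pmax(stats::rnorm(n, 0, 0.03), -0.1), 0.1)

  if (condition != "crossing") {
    t_ms <- seq(0, 1500, by = dt)
    flat <- function(y0) tibble::tibble(
      t_ms = t_ms, x_cm = jitter(length(t_ms)), y_cm = y0,
      z_cm = jitter(length(t_ms))
    )
    return(list(lead = flat(gabor_step1[2]), trail = flat(gabor_step2[2]),
                truth = list(onset_ms = NA_real_, timing_status = "no_onset")))
  }

  draw <- function(name, value) {
    if (!is.null(truth_in[[name]])) truth_in[[name]] else value
  }
  status <- draw("timing_status", {
    u <- stats::runif(1)
    if (u < gait$too_fast_rate) "too_fast"
    else if (u < gait$too_fast_rate + gait$too_slow_rate) "too_slow"
    else "valid"
  })
  onset <- draw("onset_ms", switch(
    status,
    too_fast = floor(stats::runif(1, 150, 370) / dt) * dt,
    too_slow = round(stats::runif(1, 1010, 1400) / dt) * dt,
    valid = round(rtruncnorm(1, gait$step_onset_mean, gait$step_onset_sd,
                             377.8, 1000) / dt) * dt
  ))
  onset <- round(onset / dt) * dt

  step1_x <- draw("step1_x", gabor_step1[1] +
                    stats::rnorm(1, 0, gait$placement_sd_step1))
  step1_y <- draw("step1_y", gabor_step1[2] +
                    stats::rnorm(1, 0, gait$placement_sd_step1))
  step2_x <- draw("step2_x", gabor_step2[1] +
                    stats::rnorm(1, 0, gait$placement_sd_step2))
  step2_y <- draw("step2_y", gabor_step2[2] +
                    stats::rnorm(1, 0, gait$placement_sd_step2))
  lead_clear <- draw("lead_clearance",
                     max(rtruncnorm(1, gait$lead_clear_mean,
                                    gait$lead_clear_sd),
                         1 - obstacle$height))
  trail_clear <- draw("trail_clearance",
                      max(rtruncnorm(1, gait$trail_clear_mean,
                                     gait$trail_clear_sd),
                          1 - obstacle$height))

  obs_x <- obstacle$distance
  # timeline (ms after cue onset)
  dur_sw1 <- 300; dur_sw2 <- 350; dur_cross <- 450
  t_land1 <- onset + dur_sw1            # lead completes step 1
  t_land2 <- t_land1 + dur_sw2          # trail completes step 2
  t_lead_land <- t_land2 + dur_cross    # lead lands beyond obstacle
  t_trail_land <- t_lead_land + dur_cross
  t_end <- t_trail_land + 200
  t_ms <- seq(0, t_end, by = dt)
  n <- length(t_ms)

  build_limb <- function(y_home, y_step, x_step, swing_from, swing_to,
                         cross_from, cross_to, apex, x_step_pos, initial) {
    x <- numeric(n); y <- rep(y_home, n); z <- numeric(n)
    pre <- t_ms < swing_from
    x[pre] <- jitter(sum(pre)); z[pre] <- jitter(sum(pre))
    # step swing: brisk initial displacement, raised-cosine remainder
    sw <- t_ms >= swing_from & t_ms < swing_to
    tau <- (t_ms[sw] - swing_from) / (swing_to - swing_from)
    xsw <- ifelse(
      t_ms[sw] <= swing_from + dt / 2, 0,
      initial + (x_step_pos - initial) *
        rc_profile((t_ms[sw] - (swing_from + dt)) /
                     (swing_to - swing_from - dt))
    )
    x[sw] <- xsw
    y[sw] <- y_home + (y_step - y_home) * rc_profile(tau)
    z[sw] <- 8 * sin(pi * tau)^2
    # stance on the step position
    st <- t_ms >= swing_to & t_ms < cross_from
    x[st] <- x_step_pos; y[st] <- y_step; z[st] <- 0
    # crossing swing: apex exactly above the obstacle front edge
    cr <- t_ms >= cross_from & t_ms < cross_to
    tau_c <- (t_ms[cr] - cross_from) / (cross_to - cross_from)
    x_land <- obs_x + (obs_x - x_step_pos) * 0.35 + 20
    xc <- x_step_pos + (x_land - x_step_pos) * rc_profile(tau_c)
    x[cr] <- xc
    z[cr] <- crossing_z(xc, x_step_pos, obs_x, x_land, apex)
    y[cr] <- y_step
    post <- t_ms >= cross_to
    x[post] <- x_land; y[post] <- y_step; z[post] <- 0
    tibble::tibble(t_ms = t_ms, x_cm = x, y_cm = y, z_cm = z)
  }

  lead <- build_limb(
    y_home = gabor_step1[2], y_step = step1_y,
    swing_from = onset - dt, swing_to = t_land1,
    cross_from = t_land2, cross_to = t_lead_land,
    apex = obstacle$height + lead_clear,
    x_step_pos = step1_x, initial = 1.0
  )
  trail <- build_limb(
    y_home = gabor_step2[2], y_step = step2_y,
    swing_from = t_land1, swing_to = t_land2,
    cross_from = t_lead_land, cross_to = t_trail_land,
    apex = obstacle$height + trail_clear,
    x_step_pos = step2_x, initial = 1.0
  )

  truth <- list(
    onset_ms = onset,
    timing_status = status,
    lead_hd = obs_x - step1_x,
    trail_hd = obs_x - step2_x,
    lead_clearance = lead_clear,
    trail_clearance = trail_clear,
    placement_step1 = sqrt((step1_x - gabor_step1[1])^2 +
                             (step1_y - gabor_step1[2])^2),
    placement_step2 = sqrt((step2_x - gabor_step2[1])^2 +
                             (step2_y - gabor_step2[2])^2),
    step1 = c(x = step1_x, y = step1_y),
    step2 = c(x = step2_x, y = step2_y)
  )
  list(lead = lead, trail = trail, truth = truth)
}

#' Simulate a full cohort: schedules, responses, and optional traces
#'
#' Each participant gets a freshly randomised schedule, a random baseline
#' intercept (perturbing all cell probabilities) and a random crossing-shift
#' intercept (perturbing crossing-trial probabilities only — the component
#' that survives in crossing-minus-stationary change scores and sets the
#' between-participant variance of the mixed model). Participant-level mean
#' step locations are also drawn so that across the cohort the horizontal
#' distance SDs reach the configured totals while within-participant foot
#' placement keeps its scatter around the Gabor locations.
#'
#' @param n_participants Number of participants (>= 2).
#' @param config A [session_config()].
#' @param observer An [observer_model()] template.
#' @param gait A [gait_params()].
#' @param gaze A [gaze_params()].
#' @param obstacle An [obstacle_spec()].
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @param intercept_sd Between-participant SD of the baseline probability,
#'   percentage points.
#' @param crossing_shift_sd Between-participant SD of the crossing-condition
#'   shift, percentage points.
#' @param traces Which raw traces to simulate: `"none"` (responses only),
#'   `"gaze"`, `"kinematics"` or `"all"`.
#' @param thresholds Optional named per-location orientation thresholds
#'   (degrees) used for the schedules; defaults to the observer's true
#'   79.4% thresholds.
#' @return A list of class `stepgaze_cohort` with elements `responses`
#'   (one row per trial over all participants), `gaze` (long trace tibble)
#'   and `gaze_truth`, `kin` (long trajectory tibble, `limb` column) and
#'   `kin_truth`, and `truth` (participant effects and cell probabilities).
#' @export
simulate_cohort <- function(n_participants = 12L,
                            config = session_config(),
                            observer = observer_model(),
                            gait = gait_params(),
                            gaze = gaze_params(),
                            obstacle = obstacle_spec(),
                            seed = 1L,
                            intercept_sd = 3,
                            crossing_shift_sd = sqrt(6.344),
                            traces = c("none", "gaze", "kinematics", "all"),
                            thresholds = NULL) {
  stopifnot(n_participants >= 2)
  traces <- match.arg(traces)
  if (is.null(thresholds)) thresholds <- observer$threshold79
  do_gaze <- traces %in% c("gaze", "all")
  do_kin <- traces %in% c("kinematics", "all")

  # between-participant spread of mean step locations, chosen so the total
  # horizontal-distance SD matches the gait parameters
  between_sd1 <- sqrt(max(0, gait$lead_hd_sd^2 - gait$placement_sd_step1^2))
  between_sd2 <- sqrt(max(0, gait$trail_hd_sd^2 - gait$placement_sd_step2^2))

  withr::with_seed(seed, {
    sched_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
    b <- stats::rnorm(n_participants, 0, intercept_sd) / 100
    cshift <- stats::rnorm(n_participants, 0, crossing_shift_sd) / 100
    gx1 <- stats::rnorm(n_participants, obstacle$step1_x, between_sd1)
    gx2 <- stats::rnorm(n_participants, obstacle$step2_x, between_sd2)

    responses <- vector("list", n_participants)
    gaze_long <- list(); gaze_truth <- list()
    kin_long <- list(); kin_truth <- list()

    for (i in seq_len(n_participants)) {
      cfg_i <- config
      cfg_i$seed <- sched_seeds[i]
      sched <- generate_session(cfg_i, thresholds = thresholds)
      shift <- b[i] + cshift[i] * (sched$condition == "crossing")
      resp <- simulate_responses(observer, sched, shift = shift)
      resp$participant <- sprintf("P%02d", i)
      responses[[i]] <- resp

      if (do_gaze) {
        viol <- stats::runif(nrow(sched)) < gaze$violation_rate
        traces_i <- lapply(seq_len(nrow(sched)), function(j) {
          g <- simulate_gaze(gaze, config, violation = viol[j])
          g$trace$trial_id <- sched$trial_id[j]
          g$trace
        })
        gl <- dplyr::bind_rows(traces_i)
        gl$participant <- sprintf("P%02d", i)
        gaze_long[[i]] <- gl
        gaze_truth[[i]] <- tibble::tibble(
          participant = sprintf("P%02d", i),
          trial_id = sched$trial_id, violation = viol
        )
      }
      if (do_kin) {
        cross_idx <- which(sched$condition == "crossing")
        g1y <- obstacle$lateral_offset *
          ifelse(sched$cue[cross_idx] == "right_arrow", -1, 1)
        per_trial <- lapply(seq_along(cross_idx), function(k) {
          simulate_foot_trajectories(
            gait, obstacle, "crossing",
            gabor_step1 = c(gx1[i], g1y[k]),
            gabor_step2 = c(gx2[i], -g1y[k])
          )
        })
        kl <- dplyr::bind_rows(lapply(seq_along(cross_idx), function(k) {
          tr <- per_trial[[k]]
          lead <- tr$lead; lead$limb <- "lead"
          trail <- tr$trail; trail$limb <- "trail"
          out <- dplyr::bind_rows(lead, trail)
          out$trial_id <- sched$trial_id[cross_idx[k]]
          out
        }))
        kl$participant <- sprintf("P%02d", i)
        kin_long[[i]] <- kl
        kin_truth[[i]] <- dplyr::bind_rows(lapply(seq_along(cross_idx),
                                                  function(k) {
          tr <- per_trial[[k]]$truth
          tibble::tibble(
            participant = sprintf("P%02d", i),
            trial_id = sched$trial_id[cross_idx[k]],
            onset_ms = tr$onset_ms, timing_status = tr$timing_status,
            lead_hd = tr$lead_hd, trail_hd = tr$trail_hd,
            lead_clearance = tr$lead_clearance,
            trail_clearance = tr$trail_clearance,
            placement_step1 = tr$placement_step1,
            placement_step2 = tr$placement_step2,
            gabor_step1_x = gx1[i], gabor_step1_y = g1y[k],
            gabor_step2_x = gx2[i], gabor_step2_y = -g1y[k]
          )
        }))
      }
    }
  })

  structure(list(
    responses = dplyr::bind_rows(responses),
    gaze = if (do_gaze) dplyr::bind_rows(gaze_long),
    gaze_truth = if (do_gaze) dplyr::bind_rows(gaze_truth),
    kin = if (do_kin) dplyr::bind_rows(kin_long),
    kin_truth = if (do_kin) dplyr::bind_rows(kin_truth),
    truth = list(
      participant = tibble::tibble(
        participant = sprintf("P%02d", seq_len(n_participants)),
        baseline_shift = b, crossing_shift = cshift,
        step1_x = gx1, step2_x = gx2
      ),
      observer = observer
    ),
    config = config, gait = gait, gaze_params = gaze, obstacle = obstacle,
    seed = seed
  ), class = "stepgaze_cohort")
}

#' @export
print.stepgaze_cohort <- function(x, ...) {
  cat(sprintf("<stepgaze_cohort> %d participants x %d trials (seed %d)\n",
              length(unique(x$responses$participant)),
              nrow(x$responses) / length(unique(x$responses$participant)),
              x$seed))
  cat(sprintf("  traces: gaze %s, kinematics %s\n",
              ifelse(is.null(x$gaze), "no", "yes"),
              ifelse(is.null(x$kin), "no", "yes")))
  invisible(x)
}
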