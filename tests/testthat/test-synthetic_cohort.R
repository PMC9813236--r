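test_that("degenerate cell probabilities behave deterministically", {
  obs <- observer_model(lapse = 0, baseline_p = 1, attention_delta = 0)
  sched <- generate_session(small_config(), default_thresholds)
  set.seed(1)
  out <- simulate_responses(obs, sched)
  expect_true(all(out$correct))
  expect_true(all(out$reported_side == out$gabor_side))
})

test_that("a single-trial response draw matches the cell probability", {
  obs <- observer_model()
  trial <- list(condition = "crossing", relevance = "stepping",
                step = "step1", gabor_location = "R1", gabor_side = "right",
                gabor_orientation = 4)
  set.seed(2)
  r <- simulate_response(obs, trial)
  expect_true(r$reported_side %in% c("left", "right"))
  expect_identical(r$correct, r$reported_side == "right")
  expect_error(simulate_response(obs, modifyList(trial,
                                                 list(gabor_orientation = 0))))
})

test_that("attention modulation hits only the mapped cell", {
  obs <- observer_model()   # 7.3-point deficit at stepping/step1
  p_mod <- observer_cell_p(obs, "crossing", "stepping", "step1", "R1")
  p_other <- observer_cell_p(obs, "crossing", "non_stepping", "step1", "L1")
  p_stat <- observer_cell_p(obs, "stationary", "not_applicable", "step1", "R1")
  expect_equal(p_stat - p_mod, 0.073)
  expect_equal(p_other, p_stat)

  null_obs <- observer_model(attention_delta = 0)
  expect_equal(
    observer_cell_p(null_obs, "crossing", "stepping", "step1", "R1"),
    observer_cell_p(null_obs, "crossing", "non_stepping", "step1", "R1")
  )
})

test_that("empirical cell rates converge to configured probabilities", {
  obs <- observer_model()
  n <- 2e4
  sched <- tibble::tibble(
    condition = "crossing", relevance = "stepping", step = "step1",
    gabor_location = "R1",
    gabor_side = sample(c("left", "right"), n, replace = TRUE),
    gabor_orientation = 4
  )
  set.seed(3)
  out <- simulate_responses(obs, sched)
  p_hat <- mean(out$correct)
  se <- sqrt(0.827 * 0.173 / n)
  expect_lt(abs(p_hat - (0.90 - 0.073)), 4 * se)

  # null model: stepping vs non-stepping differ only by sampling noise
  null_obs <- observer_model(attention_delta = 0)
  sched2 <- sched
  sched2$relevance <- "non_stepping"
  set.seed(4)
  a <- mean(simulate_responses(null_obs, sched)$correct)
  b <- mean(simulate_responses(null_obs, sched2)$correct)
  expect_lt(abs(a - b), 4 * sqrt(2 * 0.9 * 0.1 / n))
})

test_that("response bias shifts reports toward the favoured side", {
  biased <- observer_model(response_bias = 2)
  n <- 4000
  sched <- tibble::tibble(
    condition = "stationary", relevance = "not_applicable", step = "step1",
    gabor_location = "R1",
    gabor_side = rep(c("left", "right"), n / 2),
    gabor_orientation = 4
  )
  set.seed(5)
  out <- simulate_responses(biased, sched)
  expect_gt(mean(out$reported_side == "right"), 0.6)
})

test_that("foot trajectories embed onset, clearance and timing violations", {
  gait <- gait_params()
  # embedded onset recovered at exactly the embedded sample
  tr <- simulate_foot_trajectories(gait, truth_in = list(onset_ms = 741,
                                                         timing_status = "valid"))
  expect_equal(tr$truth$onset_ms, 740)  # snapped to the 100 Hz grid
  dev <- tr$lead$x_cm - tr$lead$x_cm[1]
  first <- tr$lead$t_ms[which(dev >= 0.5 |
                                tr$lead$z_cm - tr$lead$z_cm[1] >= 0.5)[1]]
  expect_lte(abs(first - tr$truth$onset_ms), 10)

  # drawn clearance realised at the obstacle plane
  tr2 <- simulate_foot_trajectories(gait,
                                    truth_in = list(lead_clearance = 10.0,
                                                    timing_status = "valid"))
  obst <- obstacle_spec()
  j <- which(tr2$lead$x_cm > obst$distance)[1]
  w <- (obst$distance - tr2$lead$x_cm[j - 1]) /
    (tr2$lead$x_cm[j] - tr2$lead$x_cm[j - 1])
  z_cross <- tr2$lead$z_cm[j - 1] + w * (tr2$lead$z_cm[j] - tr2$lead$z_cm[j - 1])
  expect_lt(abs(z_cross - obst$height - 10.0), 0.2)

  # injected too-fast violation lands before the Gabor offset
  tr3 <- simulate_foot_trajectories(gait,
                                    truth_in = list(timing_status = "too_fast"))
  expect_lt(tr3$truth$onset_ms, 377.8)

  # stationary trials never move beyond jitter
  st <- simulate_foot_trajectories(gait, condition = "stationary")
  expect_true(is.na(st$truth$onset_ms))
  expect_lt(max(abs(st$lead$x_cm)), 0.5)
})

test_that("gaze traces are quiet at zero noise and loud when violated", {
  g0 <- simulate_gaze(gaze_params(noise_sd = 0), violation = FALSE)
  expect_true(all(g0$trace$azimuth_deg == 0))
  expect_true(all(g0$trace$elevation_deg == 0))

  gv <- simulate_gaze(gaze_params(noise_sd = 0), violation = TRUE)
  dev <- sqrt(gv$trace$azimuth_deg^2 + gv$trace$elevation_deg^2)
  expect_gt(max(dev), 2)
  expect_true(gv$violation)
})

test_that("violation injection rate matches the configured proportion", {
  gz <- gaze_params(violation_rate = 0.05)
  set.seed(6)
  flagged <- vapply(1:1500, function(i) {
    v <- simulate_gaze(gz, violation = NULL)
    v$violation
  }, TRUE)
  se <- sqrt(0.05 * 0.95 / 1500)
  expect_lt(abs(mean(flagged) - 0.05), 4 * se)
})

test_that("cohorts are reproducible and sized correctly", {
  cfg <- small_config()
  a <- simulate_cohort(3, config = cfg, seed = 9)
  b <- simulate_cohort(3, config = cfg, seed = 9)
  c <- simulate_cohort(3, config = cfg, seed = 10)
  expect_identical(a$responses, b$responses)
  expect_false(identical(a$responses$correct, c$responses$correct))
  expect_equal(nrow(a$responses), 3 * 72)
  expect_error(simulate_cohort(1), "n_participants")
})

test_that("zero intercept variance gives identical cell probabilities", {
  co <- simulate_cohort(3, config = small_config(), seed = 11,
                        intercept_sd = 0, crossing_shift_sd = 0)
  probs <- dplyr::distinct(co$responses, participant, condition, relevance,
                           step, gabor_location, p_correct_true)
  spread <- dplyr::summarise(
    dplyr::group_by(probs, condition, relevance, step, gabor_location),
    d = diff(range(p_correct_true)), .groups = "drop")
  expect_true(all(spread$d == 0))
})

test_that("the ground-truth ledger covers every simulated trace", {
  co <- simulate_cohort(2, config = small_config(), seed = 12, traces = "all")
  expect_setequal(unique(co$gaze_truth$trial_id), 1:72)
  cross_ids <- co$responses$trial_id[co$responses$condition == "crossing" &
                                       co$responses$participant == "P01"]
  expect_setequal(
    co$kin_truth$trial_id[co$kin_truth$participant == "P01"], cross_ids)
  expect_true(all(c("onset_ms", "timing_status", "lead_clearance") %in%
                    names(co$kin_truth)))
})
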