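#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates, under a single root seed: threshold estimation by
#' interleaved staircases, cohort simulation (schedules, responses,
#' optional gaze and kinematic traces), gaze fixation QC, step-onset
#' detection and timing classification, signal-detection scoring and change
#' scores, and the mixed-model inference for each change-score outcome.
#' Trials excluded by QC or timing are retained in the outputs with a
#' reason rather than deleted, and the exclusion accounting identity
#' `total = analysed + gaze-excluded + timing-excluded` is enforced.
#'
#' When `traces = "none"` the raw trace stages are skipped (every trial is
#' treated as compliant and validly timed) and only the response pathway
#' runs — useful for calibration studies over many replicates.
#'
#' @inheritParams simulate_cohort
#' @param outcomes Change-score outcomes to model.
#' @param alpha Bonferroni-corrected alpha for the planned contrasts.
#' @return A list of class `stepgaze_run` with `report` (descriptives,
#'   exclusions, score and model tables), `manifest` (seed, hashes, row
#'   counts), and the intermediate `cohort`, `qc`, `metrics`, `scores`,
#'   `deltas`, `analyses`.
#' @export
run_pipeline <- function(n_participants = 12L,
                         config = session_config(),
                         observer = observer_model(),
                         gait = gait_params(),
                         gaze = gaze_params(),
                         obstacle = obstacle_spec(),
                         seed = 1L,
                         intercept_sd = 3,
                         crossing_shift_sd = sqrt(6.344),
                         traces = "none",
                         outcomes = c("delta_percent_correct",
                                      "delta_d_prime", "delta_beta"),
                         alpha = 0.013) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))

  thresholds <- run_interleaved_thresholding(
    function(loc, level) observer_p_correct(observer, loc, level),
    seed = seeds[1]
  )
  thr <- stats::setNames(thresholds$results$threshold,
                         thresholds$results$location)
  if (anyNA(thr)) thr[is.na(thr)] <- observer$threshold79[is.na(thr)]

  cohort <- simulate_cohort(
    n_participants = n_participants, config = config, observer = observer,
    gait = gait, gaze = gaze, obstacle = obstacle, seed = seeds[2],
    intercept_sd = intercept_sd, crossing_shift_sd = crossing_shift_sd,
    traces = traces, thresholds = thr
  )

  qc <- if (!is.null(cohort$gaze)) gaze_qc_report(cohort$gaze)
  metrics <- if (!is.null(cohort$kin)) {
    gait_metrics_report(cohort$kin, obstacle, gabor_steps = cohort$kin_truth)
  }

  scores <- bin_and_score(cohort$responses, qc = qc, timing = metrics)
  deltas <- compute_change_scores(scores)
  analyses <- stats::setNames(
    lapply(outcomes, function(oc) analyse_outcome(deltas, oc, alpha = alpha)),
    outcomes
  )

  # exclusion accounting over all trials
  n_total <- nrow(cohort$responses)
  key_all <- paste(cohort$responses$participant, cohort$responses$trial_id)
  gaze_bad <- if (is.null(qc)) character(0) else
    paste(qc$participant, qc$trial_id)[!qc$pass]
  timing_tbl <- if (is.null(metrics)) NULL else metrics
  timing_bad <- if (is.null(timing_tbl)) character(0) else
    paste(timing_tbl$participant, timing_tbl$trial_id)[
      timing_tbl$timing_status != "valid"]
  timing_bad <- setdiff(timing_bad, gaze_bad)
  excluded <- union(gaze_bad, timing_bad)
  n_analysed <- sum(!key_all %in% excluded)
  exclusions <- tibble::tibble(
    reason = c("analysed", "gaze_deviation",
               "too_fast", "too_slow", "no_onset"),
    n = c(
      n_analysed,
      length(gaze_bad),
      if (is.null(timing_tbl)) 0L else sum(
        paste(timing_tbl$participant, timing_tbl$trial_id) %in% timing_bad &
          timing_tbl$timing_status == "too_fast"),
      if (is.null(timing_tbl)) 0L else sum(
        paste(timing_tbl$participant, timing_tbl$trial_id) %in% timing_bad &
          timing_tbl$timing_status == "too_slow"),
      if (is.null(timing_tbl)) 0L else sum(
        paste(timing_tbl$participant, timing_tbl$trial_id) %in% timing_bad &
          timing_tbl$timing_status == "no_onset")
    )
  )
  exclusions$percent <- 100 * exclusions$n / n_total
  stopifnot(sum(exclusions$n) == n_total)

  gait_summary <- if (!is.null(metrics)) {
    valid <- metrics[metrics$timing_status == "valid", ]
    tibble::tibble(
      measure = c("step_onset_ms", "lead_horizontal_distance_cm",
                  "trail_horizontal_distance_cm", "lead_clearance_cm",
                  "trail_clearance_cm", "foot_placement_step1_cm",
                  "foot_placement_step2_cm"),
      mean = c(mean(valid$step_onset),
               mean(valid$lead_horizontal_distance, na.rm = TRUE),
               mean(valid$trail_horizontal_distance, na.rm = TRUE),
               mean(valid$lead_clearance, na.rm = TRUE),
               mean(valid$trail_clearance, na.rm = TRUE),
               mean(valid$foot_placement_step1, na.rm = TRUE),
               mean(valid$foot_placement_step2, na.rm = TRUE)),
      sd = c(stats::sd(valid$step_onset),
             stats::sd(valid$lead_horizontal_distance, na.rm = TRUE),
             stats::sd(valid$trail_horizontal_distance, na.rm = TRUE),
             stats::sd(valid$lead_clearance, na.rm = TRUE),
             stats::sd(valid$trail_clearance, na.rm = TRUE),
             stats::sd(valid$foot_placement_step1, na.rm = TRUE),
             stats::sd(valid$foot_placement_step2, na.rm = TRUE))
    )
  }

  model_table <- dplyr::bind_rows(lapply(outcomes, function(oc) {
    f <- analyses[[oc]]$selected
    out <- f$fixed
    out$outcome <- oc
    out$icc <- f$icc
    out$r2_marginal <- f$r2_marginal
    out$r2_conditional <- f$r2_conditional
    out
  }))

  manifest <- list(
    seed = seed,
    stage_seeds = as.integer(seeds),
    config_hash = rlang::hash(list(config, observer, gait, gaze, obstacle,
                                   n_participants, intercept_sd,
                                   crossing_shift_sd, traces)),
    digests = list(
      responses = rlang::hash(cohort$responses),
      qc = rlang::hash(qc),
      metrics = rlang::hash(metrics),
      scores = rlang::hash(scores),
      deltas = rlang::hash(deltas)
    ),
    rows = c(responses = nrow(cohort$responses),
             scores = nrow(scores), deltas = nrow(deltas)),
    exclusions = exclusions
  )

  structure(list(
    report = list(thresholds = thresholds$results,
                  gait_summary = gait_summary,
                  exclusions = exclusions,
                  scores = scores,
                  deltas = deltas,
                  model_table = model_table),
    manifest = manifest,
    cohort = cohort, qc = qc, metrics = metrics,
    scores = scores, deltas = deltas, analyses = analyses
  ), class = "stepgaze_run")
}

#' @export
print.stepgaze_run <- function(x, ...) {
  cat("<stepgaze_run>\n")
  cat("  exclusions:\n")
  print(as.data.frame(x$manifest$exclusions), row.names = FALSE, digits = 3)
  for (oc in names(x$analyses)) {
    sel <- x$analyses[[oc]]$selected
    cat(sprintf("  %s: interaction %s, ICC %.3f, R2m %.3f\n", oc,
                ifelse(sel$includes_interaction, "retained", "dropped"),
                sel$icc, sel$r2_marginal))
  }
  invisible(x)
}

#' Residual diagnostic plots for a fitted change-score model
#'
#' Normal QQ plot of residuals and residuals against fitted values, for
#' checking normality and homogeneity of variance.
#'
#' @param fit An `attention_fit`.
#' @return A list of two ggplot objects (`qq`, `residual_vs_fitted`).
#' @export
plot_model_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "attention_fit"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for diagnostic plots", call. = FALSE)
  }
  df <- data.frame(fitted = stats::fitted(fit$model),
                   residual = stats::residuals(fit$model))
  qq <- ggplot2::ggplot(df, ggplot2::aes(sample = .data$residual)) +
    ggplot2::stat_qq() + ggplot2::stat_qq_line() +
    ggplot2::labs(title = paste("QQ plot:", fit$outcome),
                  x = "theoretical quantiles", y = "residuals")
  rvf <- ggplot2::ggplot(df, ggplot2::aes(.data$fitted, .data$residual)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(title = paste("Residuals vs fitted:", fit$outcome),
                  x = "fitted", y = "residuals")
  list(qq = qq, residual_vs_fitted = rvf)
}
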