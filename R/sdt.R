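#' Classify a discrimination response in signal-detection terms
#'
#' Right-tilted Gabor patches play the role of the signal: a correct
#' response to a right-tilted patch is a hit, an incorrect one a miss; a
#' correct response to a left-tilted patch is a correct rejection, an
#' incorrect one a false alarm. Vectorised.
#'
#' @param gabor_side Presented tilt, `"left"` or `"right"`.
#' @param reported_side Reported tilt, `"left"` or `"right"`.
#' @return `"hit"`, `"miss"`, `"correct_rejection"` or `"false_alarm"`.
#' @export
classify_response <- function(gabor_side, reported_side) {
  stopifnot(all(gabor_side %in% c("left", "right")),
            all(reported_side %in% c("left", "right")))
  dplyr::case_when(
    gabor_side == "right" & reported_side == "right" ~ "hit",
    gabor_side == "right" & reported_side == "left" ~ "miss",
    gabor_side == "left" & reported_side == "left" ~ "correct_rejection",
    TRUE ~ "false_alarm"
  )
}

#' SDT count container
#'
#' @param hits,misses,correct_rejections,false_alarms Non-negative counts.
#' @return A list of class `sdt_counts`.
#' @export
sdt_counts <- function(hits, misses, correct_rejections, false_alarms) {
  counts <- c(hits = hits, misses = misses,
              correct_rejections = correct_rejections,
              false_alarms = false_alarms)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "sdt_counts")
}

#' Log-linear corrected hit and false-alarm rates
#'
#' Adds 0.5 to each numerator and 1 to each denominator, applied
#' unconditionally to every cell, so rates are strictly inside (0, 1) and
#' the normal quantiles in d-prime and beta stay finite even for perfect
#' cells. A cell with no trials yields 0.5/1 = 0.5 with a warning.
#'
#' @param counts An [sdt_counts()] (or list with the same fields).
#' @return Named numeric: `hit_rate`, `fa_rate`.
#' @export
compute_rates <- function(counts) {
  n_signal <- counts$hits + counts$misses
  n_noise <- counts$false_alarms + counts$correct_rejections
  if (n_signal == 0 || n_noise == 0) {
    warning("degenerate SDT cell: no ",
            if (n_signal == 0) "signal (right-tilted)" else
              "noise (left-tilted)",
            " trials; corrected rate falls back to 0.5", call. = FALSE)
  }
  c(hit_rate = (counts$hits + 0.5) / (n_signal + 1),
    fa_rate = (counts$false_alarms + 0.5) / (n_noise + 1))
}

#' Percent correct, d-prime and beta for one cell
#'
#' Percent correct is computed from the raw counts,
#' `100 * (hits + correct rejections) / total`. Sensitivity is
#' `d' = Z(hit rate) - Z(false-alarm rate)` and the likelihood-ratio
#' response criterion is `beta = exp((Z_fa^2 - Z_hit^2) / 2)`, both on the
#' log-linear corrected rates (`Z` is the standard-normal quantile). A
#' `d'` of 0 is chance performance; `beta` of 1 is an unbiased responder,
#' below 1 a "right"-biased one, above 1 a "left"-biased one.
#'
#' @param counts An [sdt_counts()].
#' @return A list of class `sdt_scores`: `percent_correct`, `hit_rate`,
#'   `fa_rate`, `d_prime`, `beta`, `n_trials`.
#' @export
compute_scores <- function(counts) {
  n <- counts$hits + counts$misses + counts$correct_rejections +
    counts$false_alarms
  pc <- if (n > 0) {
    100 * (counts$hits + counts$correct_rejections) / n
  } else {
    NA_real_
  }
  rates <- compute_rates(counts)
  z_hit <- stats::qnorm(rates[["hit_rate"]])
  z_fa <- stats::qnorm(rates[["fa_rate"]])
  structure(list(
    percent_correct = pc,
    hit_rate = rates[["hit_rate"]],
    fa_rate = rates[["fa_rate"]],
    d_prime = z_hit - z_fa,
    beta = exp((z_fa^2 - z_hit^2) / 2),
    n_trials = n
  ), class = "sdt_scores")
}

#' Bin valid responses and score every analysis cell per participant
#'
#' Crossing trials are binned into the four relevance-by-step cells;
#' stationary trials are binned by step only (relevance is not applicable).
#' Trials failing gaze QC or the step-timing window are excluded before
#' binning.
#'
#' @param records Response tibble (one row per trial) with `participant`,
#'   `trial_id`, `condition`, `relevance`, `step`, `gabor_side`,
#'   `reported_side`.
#' @param qc Optional gaze QC report ([gaze_qc_report()]): rows with
#'   `pass == FALSE` are excluded.
#' @param timing Optional timing table with `participant`, `trial_id`,
#'   `timing_status`: crossing rows with status other than `"valid"` are
#'   excluded.
#' @return Tibble with one row per participant x cell: counts, rates,
#'   `percent_correct`, `d_prime`, `beta`, `n_trials`.
#' @export
bin_and_score <- function(records, qc = NULL, timing = NULL) {
  keep <- rep(TRUE, nrow(records))
  key <- paste(records$participant, records$trial_id)
  if (!is.null(qc)) {
    bad <- paste(qc$participant, qc$trial_id)[!qc$pass]
    keep <- keep & !key %in% bad
  }
  if (!is.null(timing)) {
    bad <- paste(timing$participant, timing$trial_id)[
      timing$timing_status != "valid"]
    keep <- keep & !(key %in% bad & records$condition == "crossing")
  }
  records <- records[keep, ]
  records$cls <- classify_response(records$gabor_side, records$reported_side)
  records$relevance <- ifelse(records$condition == "stationary",
                              NA_character_, records$relevance)
  cells <- dplyr::summarise(
    dplyr::group_by(records, .data$participant, .data$condition,
                    .data$relevance, .data$step),
    hits = sum(.data$cls == "hit"),
    misses = sum(.data$cls == "miss"),
    correct_rejections = sum(.data$cls == "correct_rejection"),
    false_alarms = sum(.data$cls == "false_alarm"),
    .groups = "drop"
  )
  scores <- lapply(seq_len(nrow(cells)), function(i) {
    compute_scores(sdt_counts(cells$hits[i], cells$misses[i],
                              cells$correct_rejections[i],
                              cells$false_alarms[i]))
  })
  cells$percent_correct <- vapply(scores, `[[`, 0, "percent_correct")
  cells$hit_rate <- vapply(scores, `[[`, 0, "hit_rate")
  cells$fa_rate <- vapply(scores, `[[`, 0, "fa_rate")
  cells$d_prime <- vapply(scores, `[[`, 0, "d_prime")
  cells$beta <- vapply(scores, `[[`, 0, "beta")
  cells$n_trials <- vapply(scores, `[[`, 0, "n_trials")
  cells
}

#' Crossing-minus-stationary change scores
#'
#' For every crossing cell (relevance x step) of each participant, subtracts
#' the participant's stationary score for the same step. Negative values
#' mean the score was higher while remaining stationary.
#'
#' @param scores Output of [bin_and_score()] (both conditions present).
#' @return Tibble: `participant`, `relevance`, `step`,
#'   `delta_percent_correct`, `delta_d_prime`, `delta_beta`.
#' @export
compute_change_scores <- function(scores) {
  crossing <- scores[scores$condition == "crossing", ]
  stationary <- scores[scores$condition == "stationary", ]
  merged <- dplyr::left_join(
    crossing, stationary,
    by = c("participant", "step"), suffix = c("", "_stat")
  )
  missing <- is.na(merged$percent_correct_stat)
  if (any(missing)) {
    stop("missing stationary reference cell for ",
         paste(unique(paste(merged$participant[missing],
                            merged$step[missing])), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    participant = merged$participant,
    relevance = merged$relevance,
    step = merged$step,
    delta_percent_correct = merged$percent_correct -
      merged$percent_correct_stat,
    delta_d_prime = merged$d_prime - merged$d_prime_stat,
    delta_beta = merged$beta - merged$beta_stat
  )
}
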