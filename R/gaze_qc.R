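#' Per-sample angular deviation of gaze from the initial fixation
#'
#' The reference direction is the mean gaze over the first 100 ms of the
#' fixation window (damping tracker noise) or the first sample, and the
#' deviation is the small-angle Euclidean composition of the horizontal and
#' vertical offsets from it.
#'
#' @param trace Tibble with `t_ms`, `azimuth_deg`, `elevation_deg`; samples
#'   must be strictly increasing in time.
#' @param window Length-2 numeric: analysis window (ms); defaults to the
#'   full trace.
#' @param reference `"mean100"` (mean over the window's first 100 ms) or
#'   `"first"` (first in-window sample).
#' @return List with `deviation` (tibble `t_ms`, `dev_h`, `dev_v`,
#'   `dev_deg`), `reference` (h, v) and window means per plane (`mean_h`,
#'   `mean_v`).
#' @export
compute_deviation <- function(trace, window = NULL,
                              reference = c("mean100", "first")) {
  reference <- match.arg(reference)
  if (is.null(window)) window <- range(trace$t_ms)
  stopifnot(!is.unsorted(trace$t_ms, strictly = TRUE))
  inwin <- trace$t_ms >= window[1] & trace$t_ms <= window[2]
  if (!any(inwin)) stop("gaze window contains no samples", call. = FALSE)
  tw <- trace[inwin, ]
  ref_idx <- if (reference == "mean100") {
    tw$t_ms <= tw$t_ms[1] + 100
  } else {
    seq_along(tw$t_ms) == 1L
  }
  ref <- c(h = mean(tw$azimuth_deg[ref_idx]),
           v = mean(tw$elevation_deg[ref_idx]))
  dev_h <- tw$azimuth_deg - ref[["h"]]
  dev_v <- tw$elevation_deg - ref[["v"]]
  list(
    deviation = tibble::tibble(t_ms = tw$t_ms, dev_h = dev_h, dev_v = dev_v,
                               dev_deg = sqrt(dev_h^2 + dev_v^2)),
    reference = ref,
    mean_h = mean(dev_h),
    mean_v = mean(dev_v)
  )
}

#' Fixation-compliance verdict for one trial
#'
#' A trial fails if gaze deviated by more than 2 degrees in any direction
#' from the initial fixation position anywhere in the window ("more than" —
#' exactly 2 degrees passes). `mode = "composed"` thresholds the composed
#' angular magnitude (the stricter reading, default); `mode = "per_plane"`
#' thresholds each plane's absolute deviation separately.
#'
#' @inheritParams compute_deviation
#' @param limit_deg Compliance bound, degrees.
#' @param mode `"composed"` or `"per_plane"`.
#' @return List of class `fixation_verdict`: `pass`, `max_deviation` (under
#'   the selected mode), `mean_h`, `mean_v`.
#' @export
check_fixation <- function(trace, window = NULL, limit_deg = 2,
                           mode = c("composed", "per_plane"),
                           reference = "mean100") {
  mode <- match.arg(mode)
  dev <- compute_deviation(trace, window, reference)
  max_dev <- if (mode == "composed") {
    max(dev$deviation$dev_deg)
  } else {
    max(abs(c(dev$deviation$dev_h, dev$deviation$dev_v)))
  }
  structure(list(pass = max_dev <= limit_deg, max_deviation = max_dev,
                 mean_h = dev$mean_h, mean_v = dev$mean_v, mode = mode),
            class = "fixation_verdict")
}

#' @export
print.fixation_verdict <- function(x, ...) {
  cat(sprintf("<fixation_verdict> %s (max deviation %.2f deg, %s)\n",
              ifelse(x$pass, "PASS", "FAIL"), x$max_deviation, x$mode))
  invisible(x)
}

#' Gaze QC report for a cohort's traces
#'
#' Applies [check_fixation()] to every (participant, trial) trace.
#'
#' @param gaze_long Long gaze tibble with `participant`, `trial_id`, `t_ms`,
#'   `azimuth_deg`, `elevation_deg`.
#' @inheritParams check_fixation
#' @return Tibble: `participant`, `trial_id`, `pass`, `max_deviation`,
#'   `mean_h`, `mean_v`, `reason` (`"gaze_deviation"` or `NA`).
#' @export
gaze_qc_report <- function(gaze_long, limit_deg = 2, mode = "composed",
                           reference = "mean100") {
  keys <- dplyr::distinct(gaze_long, .data$participant, .data$trial_id)
  grouped <- split(gaze_long,
                   paste(gaze_long$participant, gaze_long$trial_id))
  rows <- lapply(grouped, function(tr) {
    v <- check_fixation(tr, limit_deg = limit_deg, mode = mode,
                        reference = reference)
    tibble::tibble(participant = tr$participant[1],
                   trial_id = tr$trial_id[1],
                   pass = v$pass, max_deviation = v$max_deviation,
                   mean_h = v$mean_h, mean_v = v$mean_v,
                   reason = ifelse(v$pass, NA_character_, "gaze_deviation"))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$participant, .data$trial_id)
}
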