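#' PET frame schedule
#'
#' A contiguous, non-overlapping sequence of acquisition frames starting at
#' time 0, described by per-frame durations in minutes.
#'
#' @param durations_min frame durations, minutes (all > 0).
#' @return A data frame of class `frame_schedule` with columns `start` and
#'   `duration` (minutes).
#' @export
frame_schedule <- function(durations_min) {
  stop_field(is.numeric(durations_min) && length(durations_min) >= 1 &&
               all(is.finite(durations_min)) && all(durations_min > 0),
             "durations_min", "must be positive finite durations")
  out <- data.frame(start = cumsum(c(0, durations_min[-length(durations_min)])),
                    duration = durations_min)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' The 18-frame dynamic D1 PET schedule
#'
#' 9 frames of 2 min, 3 of 3 min, 3 of 4.2 min and 3 of 5 min, totalling
#' 54.6 min — the acquisition protocol assumed by the default Logan window.
#'
#' @return A [frame_schedule()].
#' @export
pet_frame_schedule <- function() {
  frame_schedule(c(rep(2, 9), rep(3, 3), rep(4.2, 3), rep(5, 3)))
}

#' Frame midpoint times
#'
#' @param schedule a [frame_schedule()].
#' @return Midpoint of each frame (`start + duration / 2`), minutes.
#' @export
frame_midpoints <- function(schedule) {
  schedule$start + schedule$duration / 2
}

#' Time-activity curve
#'
#' Framewise mean radioactivity (arbitrary units, decay-corrected to scan
#' start) for one ROI, paired with its frame schedule.
#'
#' @param schedule a [frame_schedule()].
#' @param activity per-frame mean activity; finite, non-negative, one value
#'   per frame.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, activity) {
  if (!inherits(schedule, "frame_schedule")) stop("`schedule` must be a frame_schedule", call. = FALSE)
  stop_field(length(activity) == nrow(schedule), "activity", "length must match the schedule")
  stop_field(all(is.finite(activity)) && all(activity >= 0), "activity",
             "must be finite and non-negative")
  structure(list(schedule = schedule, activity = as.numeric(activity)), class = "tac")
}

#' Running integral of a time-activity curve at frame midpoints
#'
#' Trapezoidal integral of the piecewise activity curve from time 0 (where
#' activity is taken as 0) to each frame midpoint, with frame values treated
#' as located at midpoints.
#'
#' @param x a [tac()].
#' @return Numeric vector, one integral per frame.
#' @export
cumulative_integral <- function(x) {
  if (!inherits(x, "tac")) stop("`x` must be a tac", call. = FALSE)
  t <- c(0, frame_midpoints(x$schedule))
  y <- c(0, x$activity)
  cumtrapz1(t, y)[-1L]
}

same_schedule <- function(a, b) {
  nrow(a) == nrow(b) && max(abs(a$start - b$start), abs(a$duration - b$duration)) < 1e-9
}

#' Logan graphical estimate of the distribution volume ratio
#'
#' Non-invasive Logan analysis with a reference-tissue input and no k2'
#' correction term: over frames whose midpoints fall inside `window`, the
#' slope of `int_0^t C_T / C_T(t)` against `int_0^t C_ref / C_T(t)` is the
#' DVR. A `k2_ref` value can optionally be supplied to add the standard
#' `C_ref(t) / k2_ref` term to the integrated reference input.
#'
#' @param target,reference [tac()] objects sharing one schedule.
#' @param window inclusive time window in minutes (default 18–55).
#' @param k2_ref optional reference-tissue clearance constant (1/min) for
#'   the intercept-corrected variant; `NULL` (default) omits the term.
#' @return A list of class `logan_fit`: `dvr`, `bp` (`dvr - 1`),
#'   `intercept`, `r2` of the Logan line, and `n_points`.
#' @export
logan_dvr <- function(target, reference, window = c(18, 55), k2_ref = NULL) {
  if (!inherits(target, "tac") || !inherits(reference, "tac")) {
    stop("`target` and `reference` must be tac objects", call. = FALSE)
  }
  if (!same_schedule(target$schedule, reference$schedule)) {
    stop("target and reference must share one frame schedule", call. = FALSE)
  }
  stop_field(length(window) == 2L && window[1L] < window[2L], "window",
             "must be c(start, end) minutes with start < end")
  mid <- frame_midpoints(target$schedule)
  if (max(mid) <= window[1L]) {
    stop(sprintf("frame schedule ends before the Logan window starts (%.1f min)",
                 window[1L]), call. = FALSE)
  }
  keep <- mid >= window[1L] & mid <= window[2L]
  if (sum(keep) < 3L) stop("need at least 3 frame midpoints inside the window", call. = FALSE)
  ct <- target$activity[keep]
  if (any(ct <= 0)) stop("target activity must be positive inside the Logan window", call. = FALSE)
  int_t <- cumulative_integral(target)[keep]
  int_r <- cumulative_integral(reference)[keep]
  x <- int_r / ct
  if (!is.null(k2_ref)) x <- x + reference$activity[keep] / (k2_ref * ct)
  y <- int_t / ct
  vx <- stats::var(x)
  if (!is.finite(vx) || vx < 1e-12 * max(1, mean(x)^2)) {
    stop("degenerate Logan regressor: no variance in normalized integrated reference",
         call. = FALSE)
  }
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  r2 <- stats::cor(x, y)^2
  structure(list(dvr = slope, bp = slope - 1, intercept = intercept,
                 r2 = r2, n_points = sum(keep), window = window),
            class = "logan_fit")
}

#' Binding potential from a distribution volume ratio
#'
#' @param dvr finite DVR value(s).
#' @return `dvr - 1`.
#' @export
bp_from_dvr <- function(dvr) {
  stop_field(all(is.finite(dvr)), "dvr", "must be finite")
  dvr - 1
}

#' Logan BP table over a set of ROI time-activity curves
#'
#' Applies [logan_dvr()] to every non-cerebellar ROI against the reference
#' curve. Because the reference region (cerebellum) defines the input
#' function, cerebellar ROIs are excluded from the output table.
#'
#' @param tacs named list of [tac()] objects, one per ROI.
#' @param reference the reference-region [tac()].
#' @param cerebellar_ids character vector of ROI names to exclude.
#' @param window Logan window, minutes.
#' @return A data frame with one row per analysed ROI: `roi`, `dvr`, `bp`,
#'   `r2`, `n_points`, and `negative_bp` flagging noise-driven negative
#'   estimates.
#' @export
roi_bp_table <- function(tacs, reference, cerebellar_ids = character(),
                         window = c(18, 55)) {
  if (is.null(names(tacs)) || any(!nzchar(names(tacs)))) {
    stop("`tacs` must be a named list of tac objects", call. = FALSE)
  }
  missing <- names(tacs)[!vapply(tacs, inherits, logical(1), what = "tac")]
  if (length(missing)) {
    stop(sprintf("missing or invalid TACs for ROIs: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  keep <- setdiff(names(tacs), cerebellar_ids)
  rows <- lapply(keep, function(id) {
    fit <- logan_dvr(tacs[[id]], reference, window = window)
    data.frame(roi = id, dvr = fit$dvr, bp = fit$bp, r2 = fit$r2,
               n_points = fit$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$negative_bp <- out$bp < 0
  out
}
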