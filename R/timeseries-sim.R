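#' Describe the head-motion contamination model for simulated series
#'
#' Motion is simulated as a slow random-walk jitter on all six rigid-body
#' parameters plus occasional spikes: at a spike the trace takes a step
#' displacement (so framewise displacement flags the frame) and a shared
#' artifact burst is injected into every ROI signal (so scrubbing and global
#' signal regression have a real artifact to remove).
#'
#' @param spike_rate per-volume probability of a motion spike.
#' @param spike_amp_mm translation step size at a spike (mm); the rotation
#'   step is `spike_amp_mm / 50` radians (equivalent displacement on a 50 mm
#'   sphere).
#' @param jitter_sd per-volume random-walk increment SD (mm or radians).
#' @param artifact_amp amplitude of the shared signal burst at spike frames,
#'   in units of the BOLD noise SD.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(spike_rate = 0.02, spike_amp_mm = 0.6,
                         jitter_sd = 0.002, artifact_amp = 3) {
  stop_field(spike_rate >= 0 && spike_rate <= 1, "spike_rate", "must be in [0, 1]")
  stop_field(spike_amp_mm >= 0, "spike_amp_mm", "must be >= 0")
  stop_field(jitter_sd >= 0, "jitter_sd", "must be >= 0")
  structure(list(spike_rate = spike_rate, spike_amp_mm = spike_amp_mm,
                 jitter_sd = jitter_sd, artifact_amp = artifact_amp),
            class = "motion_model")
}

#' A motion model that produces no motion at all
#' @return A `motion_model` with all amplitudes zero.
#' @export
zero_motion <- function() motion_model(0, 0, 0, 0)

#' Simulate ROI time series with a target connectome and motion artifacts
#'
#' Generates multivariate-normal BOLD-like series whose population
#' correlation matrix is the nearest valid correlation matrix to
#' `tanh(target_z)` (edge-wise targets need not be jointly realizable; the
#' projection distance is reported). White-matter and CSF nuisance signals
#' are mixed into every ROI with weight `nuisance_loading`, and the motion
#' model adds spike artifacts shared across ROIs.
#'
#' @param target_z symmetric matrix of target Fisher-z values (diagonal
#'   ignored).
#' @param n_volumes number of volumes (>= 50).
#' @param tr repetition time in seconds.
#' @param motion a [motion_model()].
#' @param nuisance_loading weight of the WM/CSF nuisance signals in each ROI
#'   (0 disables).
#' @param seed integer seed.
#' @return A list with `series` (volumes x ROIs matrix), `motion`
#'   (volumes x 6 trace: 3 translations mm, 3 rotations radians), `wm`,
#'   `csf` (nuisance signals), `spike_frames`, and `projection_distance`
#'   (Frobenius distance between `tanh(target_z)` and the correlation
#'   matrix actually sampled from).
#' @export
simulate_timeseries <- function(target_z, n_volumes, tr = 2,
                                motion = motion_model(),
                                nuisance_loading = 0.3, seed = NULL) {
  if (inherits(target_z, "connectome")) target_z <- target_z$z
  stop_field(is.matrix(target_z) && nrow(target_z) == ncol(target_z),
             "target_z", "must be a square matrix")
  if (any(!is.finite(target_z[row(target_z) != col(target_z)]))) {
    stop("`target_z` has non-finite entries", call. = FALSE)
  }
  stop_field(n_volumes >= 50, "n_volumes", "need at least 50 volumes")
  p <- ncol(target_z)
  r <- tanh((target_z + t(target_z)) / 2)
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    R <- as.matrix(Matrix::nearPD(r, corr = TRUE, eig.tol = 1e-7,
                                  conv.tol = 1e-9, maxit = 200)$mat)
  } else {
    R <- r
  }
  projection_distance <- sqrt(sum((R - r)^2))
  L <- chol(R + diag(1e-10, p))
  labels <- colnames(target_z)
  if (is.null(labels)) labels <- sprintf("roi_%d", seq_len(p))

  with_seed(seed, {
    series <- matrix(stats::rnorm(n_volumes * p), n_volumes, p) %*% L
    colnames(series) <- labels

    # AR(1) nuisance compartment signals, unit-variance scale
    ar1 <- function(n) {
      x <- as.numeric(stats::filter(stats::rnorm(n), 0.9, method = "recursive"))
      x / stats::sd(x)
    }
    wm <- ar1(n_volumes)
    csf <- ar1(n_volumes)
    if (nuisance_loading > 0) {
      series <- series + nuisance_loading * (wm + csf)
    }

    trace <- matrix(0, n_volumes, 6)
    colnames(trace) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    spike_frames <- integer(0)
    if (motion$jitter_sd > 0) {
      trace <- apply(matrix(stats::rnorm(n_volumes * 6, 0, motion$jitter_sd),
                            n_volumes, 6), 2, cumsum)
      trace[, 4:6] <- trace[, 4:6] / 50  # rotations jitter on a comparable scale
      colnames(trace) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    }
    if (motion$spike_rate > 0) {
      spike_frames <- which(stats::runif(n_volumes) < motion$spike_rate)
      spike_frames <- spike_frames[spike_frames > 1L]
      for (s in spike_frames) {
        axis_t <- sample(1:3, 1L)
        axis_r <- sample(4:6, 1L)
        step_t <- motion$spike_amp_mm * sample(c(-1, 1), 1L)
        trace[s:n_volumes, axis_t] <- trace[s:n_volumes, axis_t] + step_t
        trace[s:n_volumes, axis_r] <- trace[s:n_volumes, axis_r] + step_t / 50
        hit <- s:min(s + 1L, n_volumes)
        series[hit, ] <- series[hit, ] +
          motion$artifact_amp * stats::rnorm(1) *
            matrix(1, length(hit), p)
      }
    }
    list(series = series, motion = trace, wm = wm, csf = csf,
         spike_frames = spike_frames, tr = tr,
         projection_distance = projection_distance)
  })
}
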