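#' Pipeline configuration for connectome construction
#'
#' Collects the preprocessing constants: scrubbing threshold and window,
#' subject-inclusion rule, band-pass edges, repetition time, global signal
#' regression flag and ROI coverage threshold. Defaults correspond to a
#' task-fMRI protocol (FD threshold 0.3 mm, at least 300 surviving volumes);
#' use `rs_pipeline_config()` for a short resting-state run (0.4 mm, more
#' than 130 volumes).
#'
#' @param fd_threshold framewise-displacement scrub threshold, mm.
#' @param min_volumes minimum surviving volume count for inclusion.
#' @param inclusion_rule `">="` (at least `min_volumes`) or `">"` (strictly
#'   more than `min_volumes`).
#' @param scrub_extend `c(n_before, n_after)` frames removed around each
#'   flagged frame.
#' @param band band-pass edges, Hz.
#' @param tr repetition time, seconds.
#' @param gsr logical; include the global mean signal as a nuisance
#'   regressor.
#' @param coverage_threshold minimum fraction of ROI volume with usable
#'   signal.
#' @param head_radius_mm sphere radius converting rotations to displacement.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fd_threshold = 0.3, min_volumes = 300,
                            inclusion_rule = c(">=", ">"),
                            scrub_extend = c(1, 2), band = c(0.009, 0.1),
                            tr = 2, gsr = FALSE, coverage_threshold = 0.5,
                            head_radius_mm = 50) {
  inclusion_rule <- match.arg(inclusion_rule)
  stop_field(fd_threshold > 0, "fd_threshold", "must be > 0")
  stop_field(min_volumes > 0, "min_volumes", "must be > 0")
  stop_field(length(band) == 2L && band[1L] > 0 && band[1L] < band[2L],
             "band", "need 0 < low < high")
  stop_field(band[2L] < 1 / (2 * tr), "band", "high cutoff must be below Nyquist")
  structure(list(fd_threshold = fd_threshold, min_volumes = min_volumes,
                 inclusion_rule = inclusion_rule, scrub_extend = scrub_extend,
                 band = band, tr = tr, gsr = gsr,
                 coverage_threshold = coverage_threshold,
                 head_radius_mm = head_radius_mm),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param ... overrides passed to [pipeline_config()].
#' @export
rs_pipeline_config <- function(...) {
  args <- utils::modifyList(list(fd_threshold = 0.4, min_volumes = 130,
                                 inclusion_rule = ">"), list(...))
  do.call(pipeline_config, args)
}

#' Framewise displacement from a rigid-body motion trace
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus the rotation differences (radians) converted to
#' arc length on a sphere of `head_radius_mm`. The first frame has FD 0 by
#' convention.
#'
#' @param trace numeric matrix, volumes x 6 (3 translations mm, 3 rotations
#'   radians).
#' @param head_radius_mm sphere radius, mm.
#' @return Numeric vector of per-volume FD (mm), first element 0.
#' @export
framewise_displacement <- function(trace, head_radius_mm = 50) {
  trace <- as.matrix(trace)
  stop_field(ncol(trace) == 6L, "trace", "must have 6 columns (3 translations, 3 rotations)")
  stop_field(nrow(trace) >= 2L, "trace", "need at least 2 volumes")
  if (any(!is.finite(trace))) stop("motion trace has non-finite values", call. = FALSE)
  d <- abs(diff(trace))
  c(0, rowSums(d[, 1:3, drop = FALSE]) + head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Volume keep-mask from framewise displacement
#'
#' A volume is removed iff its FD exceeds `threshold`, or it lies within
#' `extend[1]` frames before or `extend[2]` frames after such a volume
#' (window clipped at the series ends). Default window: the previous and the
#' two next volumes.
#'
#' @param fd per-volume FD series (mm).
#' @param threshold FD threshold, mm (> 0).
#' @param extend `c(n_before, n_after)`.
#' @return Logical keep-mask, `TRUE` for retained volumes.
#' @export
scrub_mask <- function(fd, threshold, extend = c(1, 2)) {
  stop_field(threshold > 0, "threshold", "must be > 0")
  stop_field(length(extend) == 2L && all(extend >= 0), "extend",
             "must be c(n_before, n_after), both >= 0")
  n <- length(fd)
  remove <- rep(FALSE, n)
  for (t in which(fd > threshold)) {
    remove[max(1L, t - extend[1L]):min(n, t + extend[2L])] <- TRUE
  }
  !remove
}

#' Subject inclusion after scrubbing
#'
#' @param keep_mask logical keep-mask from [scrub_mask()].
#' @param min_volumes inclusion cutoff.
#' @param rule `">="`: included with at least `min_volumes` surviving
#'   volumes (task protocol); `">"`: included with strictly more (short
#'   resting-state protocol).
#' @return `TRUE` if the subject is included.
#' @export
subject_inclusion <- function(keep_mask, min_volumes, rule = c(">=", ">")) {
  rule <- match.arg(rule)
  stop_field(min_volumes > 0, "min_volumes", "must be > 0")
  n <- sum(keep_mask)
  if (rule == ">=") n >= min_volumes else n > min_volumes
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least-squares removal of the 24-parameter motion model (6
#' rigid-body parameters, their backward-difference temporal derivatives,
#' and the squares of those 12 series) plus white-matter and CSF signals,
#' optionally plus the global mean signal, from every ROI column. Collinear
#' design columns are dropped with a warning.
#'
#' @param series volumes x ROIs matrix.
#' @param trace volumes x 6 motion parameter matrix.
#' @param wm_signal,csf_signal nuisance compartment signals (same length as
#'   the series).
#' @param gsr logical; also regress the global (row-mean) signal.
#' @return Residual series of the same dimension, column means removed.
#' @export
regress_confounds <- function(series, trace, wm_signal, csf_signal, gsr = FALSE) {
  series <- as.matrix(series)
  trace <- as.matrix(trace)
  n <- nrow(series)
  stop_field(nrow(trace) == n, "trace", "row count must match the series")
  stop_field(length(wm_signal) == n, "wm_signal", "length must match the series")
  stop_field(length(csf_signal) == n, "csf_signal", "length must match the series")
  deriv <- rbind(0, diff(trace))
  twelve <- cbind(trace, deriv)
  design <- cbind(1, twelve, twelve^2, wm_signal, csf_signal)
  if (gsr) design <- cbind(design, rowMeans(series))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    drop_idx <- qr_d$pivot[seq.int(qr_d$rank + 1L, ncol(design))]
    warning(sprintf("dropping %d collinear confound column(s)", length(drop_idx)))
    design <- design[, -drop_idx, drop = FALSE]
    qr_d <- qr(design)
  }
  resid <- qr.resid(qr_d, series)
  dimnames(resid) <- dimnames(series)
  resid
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain ideal filter: Fourier components with frequency inside
#' `[low, high]` Hz are kept unchanged, all others (including DC) are
#' zeroed, and the series is transformed back. The operation is zero-phase
#' by construction.
#'
#' @param series numeric vector or volumes x ROIs matrix.
#' @param low,high passband edges, Hz.
#' @param tr repetition time, seconds.
#' @return Filtered series of the same shape.
#' @export
bandpass <- function(series, low = 0.009, high = 0.1, tr) {
  stop_field(is.numeric(tr) && tr > 0, "tr", "must be a positive repetition time")
  stop_field(low > 0 && low < high, "low", "need 0 < low < high")
  if (high > 1 / (2 * tr) + 1e-12) {
    stop("high cutoff is above the Nyquist frequency", call. = FALSE)
  }
  x <- as.matrix(series)
  n <- nrow(x)
  stop_field(n >= 50, "series", "need at least 50 volumes for band-pass filtering")
  freq <- seq_len(n) - 1L
  freq <- pmin(freq, n - freq) / (n * tr)  # two-sided frequency axis
  keep <- freq >= low & freq <= high
  out <- Re(stats::mvfft(stats::mvfft(x) * keep, inverse = TRUE)) / n
  dimnames(out) <- dimnames(x)
  if (is.matrix(series)) out else drop(out)
}

#' Retain ROIs with sufficient signal coverage
#'
#' @param coverage named numeric vector of per-ROI coverage fractions in
#'   `[0, 1]`.
#' @param threshold minimum retained fraction (default 0.5).
#' @return Indices (or names, if `coverage` is named) of retained ROIs.
#' @export
roi_coverage_filter <- function(coverage, threshold = 0.5) {
  stop_field(all(coverage >= 0 & coverage <= 1), "coverage", "fractions must be in [0, 1]")
  keep <- which(coverage >= threshold)
  if (!is.null(names(coverage))) names(coverage)[keep] else keep
}

#' Compute a Fisher-z connectome from preprocessed series
#'
#' Pearson correlations between all ROI pairs over the surviving volumes,
#' Fisher-transformed with clamping at `|r| = 1 - 1e-7` so z stays finite.
#'
#' @param series volumes x ROIs matrix (at least 2 ROIs).
#' @param keep_mask optional logical keep-mask; correlations use only
#'   retained volumes (at least 3 must survive).
#' @param subject_id,meta metadata stored on the connectome.
#' @return A [connectome()].
#' @export
compute_connectome <- function(series, keep_mask = NULL,
                               subject_id = NA_character_, meta = list()) {
  series <- as.matrix(series)
  stop_field(ncol(series) >= 2L, "series", "need at least 2 ROIs")
  if (!is.null(keep_mask)) {
    stop_field(length(keep_mask) == nrow(series), "keep_mask", "length must match the series")
    series <- series[keep_mask, , drop = FALSE]
  }
  if (nrow(series) < 3L) stop("fewer than 3 surviving volumes", call. = FALSE)
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("zero-variance ROI(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  z <- fisher_z(stats::cor(series))
  diag(z) <- 0
  meta$n_volumes_used <- nrow(series)
  connectome(z, labels = colnames(series), subject_id = subject_id, meta = meta)
}

#' Run the full per-subject connectome pipeline
#'
#' Confound regression, band-pass filtering, then correlation over scrubbed
#' frames (scrubbing enters as frame selection at the correlation step).
#' Returns the connectome together with motion summaries, or marks the
#' subject excluded when too few volumes survive scrubbing.
#'
#' @param series volumes x ROIs BOLD matrix.
#' @param trace volumes x 6 motion trace.
#' @param wm_signal,csf_signal nuisance compartment signals.
#' @param config a [pipeline_config()].
#' @param subject_id subject identifier.
#' @return A list: `included` (logical), `connectome` (or `NULL`),
#'   `fd`, `keep_mask`, `mean_fd_pre`, `mean_fd_post`, `n_volumes_used`.
#' @export
process_subject <- function(series, trace, wm_signal, csf_signal,
                            config = pipeline_config(),
                            subject_id = NA_character_) {
  fd <- framewise_displacement(trace, config$head_radius_mm)
  keep <- scrub_mask(fd, config$fd_threshold, config$scrub_extend)
  included <- subject_inclusion(keep, config$min_volumes, config$inclusion_rule)
  mean_fd_pre <- mean(fd)
  mean_fd_post <- if (any(keep)) mean(fd[keep]) else NA_real_
  if (!included) {
    return(list(included = FALSE, connectome = NULL, fd = fd, keep_mask = keep,
                mean_fd_pre = mean_fd_pre, mean_fd_post = mean_fd_post,
                n_volumes_used = sum(keep)))
  }
  clean <- regress_confounds(series, trace, wm_signal, csf_signal, gsr = config$gsr)
  filtered <- bandpass(clean, config$band[1L], config$band[2L], config$tr)
  cn <- compute_connectome(filtered, keep_mask = keep, subject_id = subject_id,
                           meta = list(mean_fd_pre = mean_fd_pre,
                                       mean_fd_after_scrub = mean_fd_post,
                                       gsr = config$gsr))
  list(included = TRUE, connectome = cn, fd = fd, keep_mask = keep,
       mean_fd_pre = mean_fd_pre, mean_fd_post = mean_fd_post,
       n_volumes_used = sum(keep))
}
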