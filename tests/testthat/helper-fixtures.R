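# shared fixtures, all generated in code

small_cohort <- function(n_young = 10, n_old = 10, seed = 101) {
  make_cohort(cohort_spec(n_young = n_young, n_old = n_old), seed = seed)
}

# cohort with explicit ages/fd, for oracle tests that need full control
fixed_cohort <- function(ages, fd = rep(0.1, length(ages))) {
  data.frame(subject_id = sprintf("S%03d", seq_along(ages)),
             age = ages,
             group = factor(ifelse(ages < 45, "younger", "older"),
                            levels = c("younger", "older")),
             sex = rep_len(c("M", "F"), length(ages)),
             mean_fd = fd)
}

# a random valid connectome over n nodes
random_connectome <- function(n_nodes, seed, subject_id = "S001", sd = 0.3) {
  vals <- with_seed(seed, stats::rnorm(n_nodes * (n_nodes - 1) / 2, 0.2, sd))
  connectome_from_edges(vals, n_nodes, subject_id = subject_id)
}

# brute-force scrub oracle: enumerate, for every frame, whether any flagged
# frame has it inside its removal window
scrub_oracle <- function(fd, threshold, extend = c(1, 2)) {
  n <- length(fd)
  flagged <- which(fd > threshold)
  keep <- rep(TRUE, n)
  for (t in seq_len(n)) {
    for (f in flagged) {
      if (t >= f - extend[1] && t <= f + extend[2]) keep[t] <- FALSE
    }
  }
  keep
}

# dense-grid numerical SRTM forward simulation (independent of the closed
# form in the package): Euler/trapezoid integration of the convolution
srtm_oracle_frames <- function(dvr, r1, k2, ref_fun, schedule, dt = 0.002) {
  t_end <- max(schedule$start + schedule$duration)
  tg <- seq(0, t_end, by = dt)
  cref <- ref_fun(tg)
  k2a <- k2 / dvr
  # I(t) = int_0^t cref(u) exp(-k2a (t-u)) du, via exact per-step decay
  I <- numeric(length(tg))
  decay <- exp(-k2a * dt)
  for (i in 2:length(tg)) {
    I[i] <- I[i - 1] * decay + dt * (cref[i] + cref[i - 1] * decay) / 2
  }
  ct <- r1 * cref + (k2 - r1 * k2a) * I
  vapply(seq_len(nrow(schedule)), function(f) {
    lo <- schedule$start[f]; hi <- lo + schedule$duration[f]
    sel <- tg >= lo & tg <= hi
    mean(ct[sel])
  }, numeric(1))
}
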