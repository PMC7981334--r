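test_that("framewise displacement follows the translation/rotation formula", {
  n <- 6
  trace <- matrix(0, n, 6)
  trace[3:n, 1] <- 0.1              # single 0.1 mm step in x between frames 2 and 3
  fd <- framewise_displacement(trace)
  expect_equal(fd, c(0, 0, 0.1, 0, 0, 0))

  trace2 <- matrix(0, n, 6)
  trace2[4:n, 5] <- 0.002           # single 2 mrad rotation step
  expect_equal(framewise_displacement(trace2), c(0, 0, 0, 50 * 0.002, 0, 0))

  expect_equal(framewise_displacement(matrix(1, n, 6)), rep(0, n))
  bad <- matrix(0, n, 6); bad[2, 3] <- Inf
  expect_error(framewise_displacement(bad), "non-finite")
  expect_error(framewise_displacement(matrix(0, n, 5)), "6 columns")
})

test_that("scrub mask removes the flagged frame, one before and two after", {
  fd <- c(0, 0, 0.5, 0, 0, 0)
  expect_equal(scrub_mask(fd, 0.3), c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_true(all(scrub_mask(c(0, 0.1, 0.2, 0.1), 0.3)))
  expect_error(scrub_mask(fd, 0), "threshold")
})

test_that("scrub mask equals brute-force window enumeration", {
  with_seed(30, {
    for (i in 1:200) {
      n <- sample(10:80, 1)
      fd <- c(0, abs(rnorm(n - 1, 0.15, 0.15)))
      expect_identical(scrub_mask(fd, 0.3), scrub_oracle(fd, 0.3))
    }
  })
})

test_that("subject inclusion applies the printed comparisons exactly", {
  expect_true(subject_inclusion(rep(TRUE, 300), 300, rule = ">="))
  expect_false(subject_inclusion(rep(TRUE, 299), 300, rule = ">="))
  expect_false(subject_inclusion(rep(TRUE, 130), 130, rule = ">"))
  expect_true(subject_inclusion(rep(TRUE, 131), 130, rule = ">"))
  expect_false(subject_inclusion(logical(0), 130, rule = ">"))
})

test_that("confound regression projects out the design", {
  with_seed(31, {
    n <- 200
    trace <- matrix(cumsum(rnorm(n * 6, 0, 0.01)), n, 6)
    wm <- rnorm(n); csf <- rnorm(n)
    series <- matrix(rnorm(n * 3), n, 3)
    res <- regress_confounds(series, trace, wm, csf)
    # residuals orthogonal to every design column
    deriv <- rbind(0, diff(trace))
    design <- cbind(1, trace, deriv, cbind(trace, deriv)^2, wm, csf)
    dots <- crossprod(apply(design, 2, function(c) c / max(sqrt(sum(c^2)), 1e-12)),
                      apply(res, 2, function(c) c / sqrt(sum(c^2))))
    expect_lt(max(abs(dots)), 1e-8)
    # a series equal to a motion regressor is annihilated
    res2 <- regress_confounds(cbind(trace[, 1]), trace, wm, csf)
    expect_lt(max(abs(res2)), 1e-10)
    # an already-orthogonal series passes through unchanged
    res3 <- regress_confounds(res, trace, wm, csf)
    expect_equal(res3, res, tolerance = 1e-10)
  })
})

test_that("collinear confounds are dropped with a warning", {
  with_seed(32, {
    n <- 100
    trace <- matrix(rnorm(n * 6), n, 6)
    trace[, 2] <- trace[, 1]   # duplicate motion parameter
    expect_warning(
      regress_confounds(matrix(rnorm(n * 2), n, 2), trace, rnorm(n), rnorm(n)),
      "collinear")
  })
})

test_that("band-pass keeps the passband and kills the stopband", {
  tr <- 2
  # 500 volumes make 0.05 and 0.2 Hz exact DFT bins (no leakage)
  t <- seq_len(500) * tr
  in_band <- sin(2 * pi * 0.05 * t)
  out_band <- sin(2 * pi * 0.2 * t)
  expect_gt(max(abs(bandpass(in_band, tr = tr))) / max(abs(in_band)), 0.95)
  expect_lt(max(abs(bandpass(out_band, tr = tr))) / max(abs(out_band)), 0.1)
  expect_lt(max(abs(bandpass(rep(3, 500), tr = tr))), 1e-10)
  expect_error(bandpass(in_band, low = 0.009, high = 0.3, tr = 2), "Nyquist")
})

test_that("ROI coverage filter retains at or above threshold", {
  expect_equal(roi_coverage_filter(c(0.4, 0.6, 0.5)), c(2L, 3L))
  cov <- rep(1, 278); cov[1:17] <- 0.2
  expect_length(roi_coverage_filter(cov), 261)
  expect_equal(roi_coverage_filter(c(a = 0.9, b = 0.7)), c("a", "b"))
})

test_that("connectome computation clamps, names offenders, and hits arctanh identity", {
  with_seed(33, {
    n <- 400
    x <- rnorm(n)
    series <- cbind(roi_a = x, roi_b = x, roi_c = rnorm(n))
    cn <- compute_connectome(series)
    expect_equal(cn$z["roi_a", "roi_b"], atanh(1 - 1e-7))
    expect_true(all(is.finite(cn$z)))

    # construct an exact target correlation r = tanh(1)
    r <- tanh(1)
    e1 <- x / sd(x); e2 <- resid(lm(rnorm(n) ~ e1)); e2 <- e2 / sd(e2)
    series2 <- cbind(a = e1, b = r * e1 + sqrt(1 - r^2) * e2)
    cn2 <- compute_connectome(series2)
    expect_equal(cn2$z["a", "b"], 1, tolerance = 1e-3)

    expect_error(compute_connectome(cbind(k = rep(1, 10), j = rnorm(10))),
                 "zero-variance ROI\\(s\\): k")
    long <- matrix(rnorm(2e4), 1e4, 2)
    expect_lt(abs(compute_connectome(long)$z[1, 2]), 0.05)
  })
})

test_that("pipeline recovers generator targets on clean data", {
  z <- matrix(0, 4, 4)
  z[upper.tri(z)] <- c(0.55, 0.31, 0.2, 0.1, 0.05, 0.4)
  z <- z + t(z)
  sim <- simulate_timeseries(z, n_volumes = 1e4, motion = zero_motion(),
                             nuisance_loading = 0, seed = 34)
  cn <- compute_connectome(sim$series)
  expect_lt(max(abs(upper_tri_values(cn) - upper_tri_values(z))), 0.02)
})

test_that("GSR leaves a numerically zero global mean", {
  z <- matrix(0.3, 4, 4); diag(z) <- 0
  sim <- simulate_timeseries(z, n_volumes = 500, seed = 35)
  clean <- regress_confounds(sim$series, sim$motion, sim$wm, sim$csf, gsr = TRUE)
  expect_lt(max(abs(rowMeans(clean))), 1e-10)
})

test_that("process_subject cleans contaminated data and applies exclusion", {
  z <- matrix(0, 4, 4)
  z[upper.tri(z)] <- c(0.55, 0.31, 0.2, 0.1, 0.05, 0.4)
  z <- z + t(z)
  sim <- simulate_timeseries(z, n_volumes = 1000,
                             motion = motion_model(spike_rate = 0.05),
                             nuisance_loading = 0.4, seed = 36)
  raw_err <- max(abs(upper_tri_values(compute_connectome(sim$series)) -
                       upper_tri_values(z)))
  res <- process_subject(sim$series, sim$motion, sim$wm, sim$csf,
                         pipeline_config(min_volumes = 300), subject_id = "S1")
  expect_true(res$included)
  expect_identical(res$connectome$subject_id, "S1")
  expect_lt(max(abs(upper_tri_values(res$connectome) - upper_tri_values(z))),
            raw_err)
  expect_lt(res$mean_fd_post, res$mean_fd_pre)
  expect_equal(res$connectome$meta$n_volumes_used, res$n_volumes_used)

  # heavy motion + strict minimum: excluded, no connectome
  res2 <- process_subject(sim$series, sim$motion, sim$wm, sim$csf,
                          pipeline_config(min_volumes = 990), "S1")
  expect_false(res2$included)
  expect_null(res2$connectome)
})

test_that("connectome objects enforce symmetry and round-trip through TSV", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  cn <- connectome(m, labels = c("a", "b"), subject_id = "S9",
                   meta = list(gsr = FALSE))
  path <- tempfile(fileext = ".tsv")
  write_connectome(cn, path)
  back <- read_connectome(path)
  expect_equal(back$z, cn$z)
  expect_identical(back$subject_id, "S9")
  bad <- m; bad[1, 2] <- 2
  expect_error(connectome(bad), "symmetric")
})
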