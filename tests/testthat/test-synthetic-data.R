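test_that("make_cohort draws the two-group age structure", {
  spec <- cohort_spec(n_young = 30, n_old = 30)
  cohort <- make_cohort(spec, seed = 1)
  expect_equal(nrow(cohort), 60)
  expect_equal(as.vector(table(cohort$group)), c(30, 30))
  # group sample means within 2 SE of the design means
  expect_lt(abs(mean(cohort$age[cohort$group == "younger"]) - 24.2), 2 * 3.4 / sqrt(30))
  expect_lt(abs(mean(cohort$age[cohort$group == "older"]) - 70.8), 2 * 2.7 / sqrt(30))
  expect_true(all(cohort$age > 18))
  expect_true(all(cohort$mean_fd >= 0))
})

test_that("degenerate sd = 0 collapses ages onto the group means", {
  cohort <- make_cohort(cohort_spec(young_age_sd = 0, old_age_sd = 0), seed = 2)
  expect_true(all(cohort$age[cohort$group == "younger"] == 24.2))
  expect_true(all(cohort$age[cohort$group == "older"] == 70.8))
})

test_that("cohort generation is deterministic under a seed and validates fields", {
  spec <- cohort_spec(seed = 9)
  expect_identical(make_cohort(spec), make_cohort(spec))
  expect_error(cohort_spec(n_young = 1), "n_young")
  expect_error(cohort_spec(old_age_sd = -1), "old_age_sd")
  expect_error(cohort_spec(young_fd_mean = -0.1), "young_fd_mean")
})

test_that("edge truth covers each unordered pair exactly once", {
  for (n in c(3, 7, 20)) {
    truth <- sample_edge_truth(n, seed = 1)
    expect_equal(nrow(truth), n * (n - 1) / 2)
    expect_true(all(truth$node_i < truth$node_j))
    expect_false(anyDuplicated(truth[, c("node_i", "node_j")]) > 0)
  }
  expect_error(sample_edge_truth(2), "n_nodes")
})

test_that("zero slope scales give exactly zero aging effects", {
  cfg <- edge_effect_config(beta_mu = c(0, 0), beta_sigma = c(0, 0))
  truth <- sample_edge_truth(5, cfg, seed = 3)
  expect_true(all(truth$beta_mu == 0))
  expect_true(all(truth$beta_sigma == 0))
})

test_that("simulated edge values follow the generative moments", {
  # 1e5 subjects at a single age: sample mean and SD match the closed form
  n <- 1e5
  cohort <- fixed_cohort(rep(70, n), fd = rep(0, n))
  truth <- data.frame(node_i = 1, node_j = 2, alpha_mu = 0.3, beta_mu = -0.002,
                      alpha_sigma = log(0.1), beta_sigma = 0.01, rho = 0)
  y <- simulate_edge_values(cohort, truth, seed = 4)
  sigma_true <- 0.1 * exp(0.01 * 50)
  expect_lt(abs(mean(y) - (0.3 - 0.1)), 3 * sigma_true / sqrt(n))
  expect_lt(abs(sd(y) - sigma_true), 3 * sigma_true / sqrt(2 * n))
})

test_that("noiseless limit reduces to mean plus motion term", {
  cohort <- fixed_cohort(c(20, 25, 30, 60, 70), fd = rep(0.2, 5))
  truth <- data.frame(node_i = 1, node_j = 2, alpha_mu = 0.3, beta_mu = 0,
                      alpha_sigma = -40, beta_sigma = 0, rho = 0.5)
  y <- simulate_edge_values(cohort, truth, seed = 5)
  expect_equal(as.vector(y), rep(0.3 + 0.5 * 0.2, 5), tolerance = 1e-12)
})

test_that("time-series generator recovers target correlations", {
  z <- matrix(0, 3, 3)
  z[upper.tri(z)] <- atanh(c(0.5, 0.3, 0.2))
  z <- z + t(z)
  sim <- simulate_timeseries(z, n_volumes = 1e5, motion = zero_motion(),
                             nuisance_loading = 0, seed = 6)
  r_hat <- cor(sim$series)
  expect_lt(max(abs(r_hat[upper.tri(r_hat)] - c(0.5, 0.3, 0.2))), 0.01)
  expect_equal(sim$projection_distance, 0)
})

test_that("null targets give near-independent series and zero motion stays zero", {
  sim <- simulate_timeseries(matrix(0, 4, 4), n_volumes = 5000,
                             motion = zero_motion(), nuisance_loading = 0, seed = 7)
  r_hat <- cor(sim$series)
  expect_lt(max(abs(r_hat[upper.tri(r_hat)])), 0.05)
  expect_true(all(sim$motion == 0))
  expect_true(all(framewise_displacement(sim$motion) == 0))
})

test_that("unrealizable edge targets are projected to a valid correlation matrix", {
  # 3-cycle with z targets that cannot all hold jointly
  z <- matrix(0, 3, 3)
  z[upper.tri(z)] <- atanh(c(0.9, 0.9, -0.9))
  z <- z + t(z)
  sim <- simulate_timeseries(z, n_volumes = 200, motion = zero_motion(),
                             nuisance_loading = 0, seed = 8)
  expect_gt(sim$projection_distance, 0)
  # sampling succeeded, so the projected matrix admitted a Cholesky factor
  expect_equal(dim(sim$series), c(200L, 3L))
})

test_that("time-series generator rejects non-finite targets and short runs", {
  z <- matrix(0, 3, 3); z[1, 2] <- z[2, 1] <- NaN
  expect_error(simulate_timeseries(z, 100), "non-finite")
  expect_error(simulate_timeseries(matrix(0, 3, 3), 20), "n_volumes")
})

test_that("GMD simulation reproduces group mean differences", {
  n <- 4000
  cohort <- fixed_cohort(c(rep(24, n / 2), rep(71, n / 2)))
  nt <- data.frame(node = 1, gmd_alpha_mu = 0.6, gmd_beta_mu = -0.003,
                   gmd_alpha_sigma = log(0.04), gmd_beta_sigma = 0)
  g <- simulate_gmd(cohort, nt, seed = 10)
  diff_hat <- mean(g[cohort$age > 45, ]) - mean(g[cohort$age < 45, ])
  expect_lt(abs(diff_hat - (-0.003 * (71 - 24))), 3 * 0.04 / sqrt(n / 4))

  nt0 <- transform(nt, gmd_beta_mu = 0, gmd_beta_sigma = 0)
  g0 <- simulate_gmd(cohort, nt0, seed = 11)
  expect_lt(abs(mean(g0[cohort$age > 45, ]) - mean(g0[cohort$age < 45, ])),
            3 * 0.04 / sqrt(n / 4))
})

test_that("all generators are reproducible under a fixed seed", {
  cohort <- small_cohort()
  truth <- sample_edge_truth(6, seed = 12)
  expect_identical(truth, sample_edge_truth(6, seed = 12))
  expect_identical(simulate_edge_values(cohort, truth, seed = 13),
                   simulate_edge_values(cohort, truth, seed = 13))
  nt <- sample_node_truth(6, seed = 14)
  expect_identical(nt, sample_node_truth(6, seed = 14))
  expect_identical(simulate_gmd(cohort, nt, seed = 15),
                   simulate_gmd(cohort, nt, seed = 15))
  s1 <- simulate_timeseries(matrix(0, 3, 3), 100, seed = 16)
  s2 <- simulate_timeseries(matrix(0, 3, 3), 100, seed = 16)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$motion, s2$motion)
  t1 <- simulate_tac(2, noise_sd = 0.05, seed = 17)
  t2 <- simulate_tac(2, noise_sd = 0.05, seed = 17)
  expect_identical(t1$target$activity, t2$target$activity)
})

test_that("latent coupling induces correlated nodal aging effects", {
  latent <- with_seed(20, rnorm(40))
  truth <- sample_edge_truth(40, seed = 21, nodal_latent = latent, coupling = 0.8)
  nodal <- nodal_beta_table(truth)
  expect_gt(cor(nodal$avg_beta_mu, latent), 0.5)
  nt <- sample_node_truth(40, seed = 22, nodal_latent = latent, bp_coupling = 0.8)
  expect_gt(cor(nt$bp_beta_mu, latent), 0.5)
})
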