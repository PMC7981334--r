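test_that("objective equals the homoscedastic Gaussian NLL plus prior penalties", {
  with_seed(80, {
    n <- 40
    ages <- runif(n, 20, 75)
    y <- 0.2 - 0.001 * (ages - 20) + rnorm(n, 0, 0.15)
    th <- c(alpha_mu = 0.2, beta_mu = -0.001, alpha_sigma = log(0.15),
            beta_sigma = 0, rho = 0)
    # closed form with constants dropped: sum(log s + r^2 / (2 s^2))
    r <- y - th[1] - th[2] * (ages - 20)
    expect_equal(neg_log_posterior(th, y, ages, priors = flat_priors()),
                 sum(log(0.15) + r^2 / (2 * 0.15^2)))
    # symmetric zero-centered priors contribute zero penalty at zero parameters
    th0 <- rep(0, 5)
    expect_equal(neg_log_posterior(th0, y, ages, priors = age_model_priors()),
                 neg_log_posterior(th0, y, ages, priors = flat_priors()))
    # doubling residuals at fixed sigma quadruples the quadratic term
    quad1 <- neg_log_posterior(th, y, ages, priors = flat_priors()) - n * log(0.15)
    y2 <- (y - r) + 2 * r
    quad2 <- neg_log_posterior(th, y2, ages, priors = flat_priors()) - n * log(0.15)
    expect_equal(quad2, 4 * quad1)
    # non-finite parameters give an optimizer-safe large value
    expect_true(is.finite(neg_log_posterior(c(NA, 0, 0, 0, 0), y, ages)))
  })
})

test_that("MAP with flat priors and fixed beta_sigma, rho reduces to OLS", {
  with_seed(81, {
    for (i in 1:20) {
      n <- 60
      ages <- c(rnorm(30, 24.2, 3.4), rnorm(30, 70.8, 2.7))
      y <- rnorm(1, 0, 0.3) + rnorm(1, 0, 0.002) * (ages - 20) + rnorm(n, 0, 0.1)
      fit <- fit_map(y, ages, priors = flat_priors(),
                     fixed = c(beta_sigma = 0, rho = 0))
      ols <- lm(y ~ I(ages - 20))
      expect_lt(abs(fit$alpha_mu - coef(ols)[1]), 1e-6)
      expect_lt(abs(fit$beta_mu - coef(ols)[2]), 1e-6)
      expect_lt(abs(exp(fit$alpha_sigma) - sqrt(mean(resid(ols)^2))), 1e-6)
      expect_identical(fit$status, "converged")
      # final objective no worse than the OLS starting point
      init <- c(coef(ols)[1], coef(ols)[2], log(sqrt(mean(resid(ols)^2))), 0, 0)
      expect_lte(fit$objective,
                 neg_log_posterior(init, y, ages, priors = flat_priors()) + 1e-10)
    }
  })
})

test_that("all five parameters are recovered at large n", {
  n <- 1e4
  truth <- c(alpha_mu = 0.3, beta_mu = -0.002, alpha_sigma = log(0.1),
             beta_sigma = 0.004, rho = 0.3)
  with_seed(82, {
    ages <- c(rnorm(n / 2, 24.2, 3.4), rnorm(n / 2, 70.8, 2.7))
    fd <- abs(rnorm(n, 0.15, 0.08))
    a <- ages - 20
    sigma <- exp(truth["alpha_sigma"] + truth["beta_sigma"] * a)
    y <- truth["alpha_mu"] + truth["beta_mu"] * a + truth["rho"] * fd +
      rnorm(n, 0, sigma)
  })
  fit <- fit_map(y, ages, fd, priors = flat_priors())
  # conservative large-n standard errors from the homoscedastic analogues
  se_slope <- 0.12 / (sd(ages) * sqrt(n))
  expect_lt(abs(fit$beta_mu - truth["beta_mu"]), 3 * se_slope)
  expect_lt(abs(fit$beta_sigma - truth["beta_sigma"]),
            3 / (sd(ages) * sqrt(2 * n)))
  expect_lt(abs(fit$alpha_mu - truth["alpha_mu"]), 0.02)
  expect_lt(abs(fit$rho - truth["rho"]), 0.1)
  expect_lt(abs(exp(fit$alpha_sigma) - 0.1), 0.005)
})

test_that("adding a constant shifts the intercept and leaves slopes alone", {
  with_seed(83, {
    ages <- c(rnorm(30, 24.2, 3.4), rnorm(30, 70.8, 2.7))
    fd <- abs(rnorm(60, 0.15, 0.05))
    y <- 0.2 - 0.001 * (ages - 20) + rnorm(60, 0, 0.1)
  })
  f1 <- fit_map(y, ages, fd, priors = flat_priors())
  f2 <- fit_map(y + 5, ages, fd, priors = flat_priors())
  expect_lt(abs(f2$alpha_mu - (f1$alpha_mu + 5)), 1e-6)
  expect_lt(abs(f2$beta_mu - f1$beta_mu), 1e-6)
  expect_lt(abs(f2$beta_sigma - f1$beta_sigma), 1e-6)
  expect_lt(abs(f2$rho - f1$rho), 1e-4)
})

test_that("an age-constant cohort is flagged unidentifiable", {
  with_seed(84, {
    y <- rnorm(20, 0.3, 0.1)
    fd <- abs(rnorm(20, 0.15, 0.05))
  })
  ages <- rep(50, 20)
  f_flat <- fit_map(y, ages, fd, priors = flat_priors())
  expect_identical(f_flat$status, "unidentifiable")
  expect_equal(f_flat$beta_mu, 0)
  expect_equal(f_flat$beta_sigma, 0)
  # with proper priors the slopes are shrunk toward the prior mean 0: the MAP
  # splits the unidentified sum alpha + 30 * beta by prior precision, so beta
  # stays near zero instead of trading off freely against the intercept
  f_prior <- fit_map(y, ages, fd, priors = age_model_priors())
  expect_identical(f_prior$status, "unidentifiable")
  expect_lt(abs(f_prior$beta_mu), 0.005)
  expect_lt(abs(f_prior$beta_sigma), 0.02)
})

test_that("sd_at_age applies the exponential age scaling", {
  fit <- list(alpha_sigma = log(0.1), beta_sigma = 0, age_ref = 20)
  expect_equal(sd_at_age(fit, 20), 0.1)
  expect_equal(sd_at_age(fit, 90), 0.1)
  fit$beta_sigma <- 0.01
  expect_equal(sd_at_age(fit, 70), 0.1 * exp(0.5))
  fit$beta_sigma <- -0.02
  ages <- seq(20, 80, by = 5)
  expect_true(all(diff(sd_at_age(fit, ages)) < 0))
})

test_that("fit_all isolates failures, permutes with its input, and summarizes signs", {
  cohort <- small_cohort(12, 12, seed = 85)
  truth <- sample_edge_truth(8, seed = 86)
  y <- simulate_edge_values(cohort, truth, seed = 87)
  y[, 3] <- 1                      # constant feature: degenerate, not fatal
  tab <- fit_all(y, cohort$age, cohort$mean_fd)
  expect_equal(nrow(tab$fits), ncol(y))
  expect_identical(tab$fits$status[3], "degenerate")
  expect_true(all(tab$fits$status[-3] %in% c("converged", "no_convergence")))
  expect_true(tab$frac_beta_mu_negative >= 0 && tab$frac_beta_mu_negative <= 1)

  perm <- rev(seq_len(ncol(y)))
  tab2 <- fit_all(y[, perm], cohort$age, cohort$mean_fd)
  expect_equal(tab2$fits$feature_id, tab$fits$feature_id[perm])
  expect_equal(tab2$fits$beta_mu, tab$fits$beta_mu[perm])
})

test_that("consistency correlation matches features and detects refit agreement", {
  cohort <- small_cohort(15, 15, seed = 88)
  truth <- sample_edge_truth(10, seed = 89)
  t1 <- fit_all(simulate_edge_values(cohort, truth, seed = 90),
                cohort$age, cohort$mean_fd)
  expect_equal(consistency_correlation(t1, t1, "beta_mu"), 1)
  # two independent noisy realizations of the same truth agree positively
  t2 <- fit_all(simulate_edge_values(cohort, truth, seed = 91),
                cohort$age, cohort$mean_fd)
  expect_gt(consistency_correlation(t1, t2, "beta_mu"), 0.3)
  bad <- t1$fits; bad$feature_id <- paste0(bad$feature_id, "_x")
  expect_error(consistency_correlation(t1, bad), "feature sets")
})
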