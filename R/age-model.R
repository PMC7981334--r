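#' Weakly informative priors for the location-scale age model
#'
#' Independent normal priors centered at 0 for each of the five model
#' parameters; a scale of `Inf` (or `"flat"`) makes the prior flat so the
#' fit reduces to maximum likelihood. Default scales are wide for the
#' intercepts and modest for the slopes and the motion coefficient, which
#' regularizes without biasing the direction of aging effects.
#'
#' @param alpha_mu,beta_mu,alpha_sigma,beta_sigma,rho prior scale for each
#'   parameter (`> 0`, `Inf`, or `"flat"`).
#' @return Named numeric vector of scales, class `age_model_priors`.
#' @export
age_model_priors <- function(alpha_mu = 10, beta_mu = 0.1,
                             alpha_sigma = 10, beta_sigma = 0.1, rho = 0.1) {
  sc <- c(alpha_mu = alpha_mu, beta_mu = beta_mu, alpha_sigma = alpha_sigma,
          beta_sigma = beta_sigma, rho = rho)
  sc <- vapply(sc, function(s) if (identical(s, "flat")) Inf else as.numeric(s), numeric(1))
  stop_field(all(sc > 0), "priors", "scales must be positive (or flat)")
  structure(sc, class = "age_model_priors")
}

#' Flat priors: plain maximum likelihood
#' @return An [age_model_priors()] object with all scales infinite.
#' @export
flat_priors <- function() {
  age_model_priors(Inf, Inf, Inf, Inf, Inf)
}

param_names <- c("alpha_mu", "beta_mu", "alpha_sigma", "beta_sigma", "rho")

#' Negative log posterior of the location-scale age model
#'
#' For observations `y_s` with centered ages `a_s = age_s - age_ref` and
#' motion covariate `fd_s`, the model is `y_s = rho * fd_s + z_s` with
#' `z_s ~ N(alpha_mu + beta_mu * a_s, exp(alpha_sigma + beta_sigma * a_s))`.
#' The returned value is the negative log likelihood (additive constants
#' dropped) plus the normal prior penalties `theta^2 / (2 * scale^2)`.
#'
#' @param params named or ordered numeric vector
#'   `(alpha_mu, beta_mu, alpha_sigma, beta_sigma, rho)`.
#' @param y per-subject values (>= 5 subjects).
#' @param ages per-subject ages, years.
#' @param fd per-subject mean framewise displacement (mm); `NULL` means no
#'   motion term (`rho` is then inert).
#' @param priors an [age_model_priors()] object.
#' @param age_ref reference age (years, default 20).
#' @return Scalar objective value; non-finite parameter input yields a large
#'   finite value so optimizers can recover.
#' @export
neg_log_posterior <- function(params, y, ages, fd = NULL,
                              priors = age_model_priors(), age_ref = 20) {
  stop_field(length(y) >= 5L, "y", "need at least 5 subjects")
  stop_field(length(ages) == length(y) && all(is.finite(ages)), "ages",
             "must be finite and match y")
  if (is.null(fd)) fd <- rep(0, length(y))
  stop_field(length(fd) == length(y) && all(is.finite(fd)), "fd",
             "must be finite and match y")
  theta <- as.numeric(params)[1:5]
  if (any(!is.finite(theta))) return(1e12)
  a <- ages - age_ref
  ls <- pmin(pmax(theta[3L] + theta[4L] * a, -50), 50)
  r <- y - theta[5L] * fd - theta[1L] - theta[2L] * a
  nll <- sum(ls + 0.5 * r^2 * exp(-2 * ls))
  pen <- sum((theta / unclass(priors))^2 / 2, na.rm = TRUE)
  val <- nll + pen
  if (!is.finite(val)) 1e12 else val
}

nlp_grad <- function(theta, y, a, fd, scales) {
  ls <- pmin(pmax(theta[3L] + theta[4L] * a, -50), 50)
  e2 <- exp(-2 * ls)
  r <- y - theta[5L] * fd - theta[1L] - theta[2L] * a
  re <- r * e2
  g <- c(-sum(re), -sum(re * a),
         sum(1 - r^2 * e2), sum(a * (1 - r^2 * e2)),
         -sum(re * fd))
  g <- g + ifelse(is.finite(scales), theta / scales^2, 0)
  ifelse(is.finite(g), g, 0)
}

#' Optimizer settings for the MAP fit
#'
#' @param n_restarts number of jittered restarts added to the deterministic
#'   start (best objective wins, ties by first found).
#' @param maxit,reltol BFGS iteration cap and relative tolerance.
#' @param grad_tol gradient-norm threshold declaring convergence.
#' @param seed seed for the restart jitter.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(n_restarts = 4, maxit = 500, reltol = 1e-12,
                         grad_tol = 1e-4, seed = 1) {
  structure(list(n_restarts = n_restarts, maxit = maxit, reltol = reltol,
                 grad_tol = grad_tol, seed = seed), class = "fit_settings")
}

#' MAP fit of the location-scale age model for one feature
#'
#' Minimizes [neg_log_posterior()] with BFGS and analytic gradients,
#' initialized at the OLS solution (`alpha_mu`, `beta_mu`, `rho` from a
#' linear regression on centered age and FD; `alpha_sigma` at the log ML
#' residual SD; `beta_sigma` at 0), plus seeded jittered restarts. Any
#' parameter can be held fixed via `fixed` (e.g. `c(beta_sigma = 0,
#' rho = 0)` for a homoscedastic motion-free fit).
#'
#' @inheritParams neg_log_posterior
#' @param fixed named numeric vector of parameters to hold fixed.
#' @param settings a [fit_settings()].
#' @param feature_id identifier stored on the result.
#' @return A list of class `edge_age_fit`: the five parameters, `status`
#'   (`"converged"`, `"no_convergence"`, `"unidentifiable"`, or
#'   `"degenerate"`), `objective`, `grad_norm`, and `n`.
#' @export
fit_map <- function(y, ages, fd = NULL, priors = age_model_priors(),
                    fixed = NULL, settings = fit_settings(), age_ref = 20,
                    feature_id = NA_character_) {
  stop_field(length(y) >= 5L, "y", "need at least 5 subjects")
  n <- length(y)
  a <- ages - age_ref
  fd_in <- fd
  if (is.null(fd)) {
    fd <- rep(0, n)
    if (!("rho" %in% names(fixed))) fixed <- c(fixed, rho = 0)
  }
  scales <- unclass(priors)

  status <- NULL
  if (stats::sd(y) == 0) status <- "degenerate"
  identifiable <- length(unique(a)) >= 2L
  if (!identifiable) {
    # no age contrast: slopes only identified through their priors
    if (!is.finite(scales[["beta_mu"]])) fixed <- c(fixed, beta_mu = 0)
    if (!is.finite(scales[["beta_sigma"]])) fixed <- c(fixed, beta_sigma = 0)
    status <- "unidentifiable"
  }
  fixed <- fixed[!duplicated(names(fixed))]
  free <- setdiff(param_names, names(fixed))

  # deterministic OLS-based start
  xcols <- list(alpha_mu = rep(1, n))
  if ("beta_mu" %in% free) xcols$beta_mu <- a
  if ("rho" %in% free && stats::sd(fd) > 0) xcols$rho <- fd
  X <- do.call(cbind, xcols)
  ols <- stats::lm.fit(X, y)
  init <- c(alpha_mu = 0, beta_mu = 0, alpha_sigma = 0, beta_sigma = 0, rho = 0)
  coefs <- ols$coefficients
  coefs[is.na(coefs)] <- 0
  init[names(xcols)] <- coefs
  rms <- sqrt(mean(ols$residuals^2))
  init["alpha_sigma"] <- log(max(rms, 1e-8))
  init[names(fixed)] <- fixed

  theta_full <- init
  obj <- function(par_free) {
    theta_full[free] <- par_free
    neg_log_posterior(theta_full, y, ages, fd, priors, age_ref)
  }
  grad <- function(par_free) {
    theta_full[free] <- par_free
    nlp_grad(theta_full, y, a, fd, scales)[match(free, param_names)]
  }

  jitter_scale <- c(alpha_mu = 0.2, beta_mu = 0.005, alpha_sigma = 0.5,
                    beta_sigma = 0.005, rho = 0.1)
  starts <- list(init[free])
  if (settings$n_restarts > 0 && length(free) > 0) {
    starts <- c(starts, with_seed(settings$seed, {
      lapply(seq_len(settings$n_restarts), function(i) {
        init[free] + stats::rnorm(length(free), 0, jitter_scale[free])
      })
    }))
  }

  best <- NULL
  if (length(free) == 0L) {
    best <- list(par = numeric(0), value = obj(numeric(0)), convergence = 0L)
  } else {
    for (st in starts) {
      res <- tryCatch(
        stats::optim(st, obj, grad, method = "BFGS",
                     control = list(maxit = settings$maxit,
                                    reltol = settings$reltol)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value - 1e-12) best <- res
    }
    if (is.null(best)) {
      return(structure(c(as.list(init),
                         list(feature_id = feature_id, status = "error",
                              objective = NA_real_, grad_norm = NA_real_, n = n)),
                       class = "edge_age_fit"))
    }
  }
  if (length(free) > 0L) {
    # polish: BFGS resets its Hessian approximation, often shaving the last
    # gradient digits after a long first run
    polish <- tryCatch(
      stats::optim(best$par, obj, grad, method = "BFGS",
                   control = list(maxit = settings$maxit,
                                  reltol = settings$reltol)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  theta_full[free] <- best$par
  gnorm <- if (length(free)) {
    sqrt(sum(grad(best$par)^2)) / max(1, sqrt(n))
  } else 0
  if (is.null(status)) {
    status <- if (gnorm < settings$grad_tol) "converged" else "no_convergence"
  }
  structure(c(as.list(theta_full),
              list(feature_id = feature_id, status = status,
                   objective = best$value, grad_norm = gnorm, n = n,
                   age_ref = age_ref, has_fd = !is.null(fd_in))),
            class = "edge_age_fit")
}

#' @export
print.edge_age_fit <- function(x, ...) {
  cat(sprintf("<edge_age_fit %s> alpha_mu=%.4g beta_mu=%.4g alpha_sigma=%.4g beta_sigma=%.4g rho=%.4g [%s]\n",
              x$feature_id, x$alpha_mu, x$beta_mu, x$alpha_sigma, x$beta_sigma,
              x$rho, x$status))
  invisible(x)
}

#' Fit the age model to every feature of a value table
#'
#' Applies [fit_map()] to each column of a subjects-by-features matrix
#' (edges for FC, nodes for BP or GMD). Per-feature failures are isolated:
#' the row is kept with `status = "error"` and `NA` parameters.
#'
#' @param values subjects x features numeric matrix (column names become
#'   feature ids).
#' @param ages,fd per-subject covariates.
#' @inheritParams fit_map
#' @param verbose print progress every 1000 features.
#' @return An object of class `aging_effect_table`: a list with `fits` (one
#'   row per feature: the five parameters, `status`, `objective`),
#'   `frac_beta_mu_negative`, `frac_beta_sigma_positive` (fractions over
#'   usable fits), `priors` and `age_ref`.
#' @export
fit_all <- function(values, ages, fd = NULL, priors = age_model_priors(),
                    fixed = NULL, settings = fit_settings(), age_ref = 20,
                    verbose = FALSE) {
  values <- as.matrix(values)
  stop_field(nrow(values) == length(ages), "values",
             "row count must equal the number of subjects")
  ids <- colnames(values)
  if (is.null(ids)) ids <- sprintf("f%d", seq_len(ncol(values)))
  rows <- vector("list", ncol(values))
  for (j in seq_len(ncol(values))) {
    fit <- tryCatch(
      fit_map(values[, j], ages, fd, priors, fixed, settings, age_ref,
              feature_id = ids[j]),
      error = function(e) {
        structure(list(alpha_mu = NA_real_, beta_mu = NA_real_,
                       alpha_sigma = NA_real_, beta_sigma = NA_real_,
                       rho = NA_real_, feature_id = ids[j], status = "error",
                       objective = NA_real_, grad_norm = NA_real_,
                       n = length(ages)), class = "edge_age_fit")
      })
    rows[[j]] <- data.frame(feature_id = fit$feature_id,
                            alpha_mu = fit$alpha_mu, beta_mu = fit$beta_mu,
                            alpha_sigma = fit$alpha_sigma,
                            beta_sigma = fit$beta_sigma, rho = fit$rho,
                            status = fit$status, objective = fit$objective,
                            stringsAsFactors = FALSE)
    if (verbose && j %% 1000L == 0L) {
      message(sprintf("fit_all: %d / %d features", j, ncol(values)))
    }
  }
  fits <- do.call(rbind, rows)
  usable <- fits$status %in% c("converged", "no_convergence")
  structure(list(
    fits = fits,
    frac_beta_mu_negative = mean(fits$beta_mu[usable] < 0),
    frac_beta_sigma_positive = mean(fits$beta_sigma[usable] > 0),
    n_features = nrow(fits), n_usable = sum(usable),
    priors = priors, age_ref = age_ref
  ), class = "aging_effect_table")
}

#' @export
print.aging_effect_table <- function(x, ...) {
  cat(sprintf("<aging_effect_table> %d features (%d usable): %.1f%% beta_mu < 0, %.1f%% beta_sigma > 0\n",
              x$n_features, x$n_usable, 100 * x$frac_beta_mu_negative,
              100 * x$frac_beta_sigma_positive))
  invisible(x)
}

#' Model-implied standard deviation at an age
#'
#' @param fit an `edge_age_fit` (or anything with `alpha_sigma`,
#'   `beta_sigma` and optionally `age_ref` entries).
#' @param age age in years.
#' @return `exp(alpha_sigma + beta_sigma * (age - age_ref))`; the SD grows
#'   (shrinks) by a factor `exp(beta_sigma)` per year.
#' @export
sd_at_age <- function(fit, age) {
  age_ref <- if (!is.null(fit$age_ref)) fit$age_ref else 20
  exp(fit$alpha_sigma + fit$beta_sigma * (age - age_ref))
}

#' Consistency of aging-effect estimates across experiments
#'
#' Pearson correlation between the per-feature `beta_mu` (or `beta_sigma`)
#' estimates of two fits over the same feature set.
#'
#' @param table_a,table_b [fit_all()] results (or their `fits` data frames)
#'   with matching `feature_id` sets.
#' @param which `"beta_mu"` or `"beta_sigma"`.
#' @return Pearson correlation coefficient.
#' @export
consistency_correlation <- function(table_a, table_b,
                                    which = c("beta_mu", "beta_sigma")) {
  which <- match.arg(which)
  fa <- if (inherits(table_a, "aging_effect_table")) table_a$fits else table_a
  fb <- if (inherits(table_b, "aging_effect_table")) table_b$fits else table_b
  if (!setequal(fa$feature_id, fb$feature_id)) {
    stop("feature sets do not match between the two tables", call. = FALSE)
  }
  fb <- fb[match(fa$feature_id, fb$feature_id), ]
  stats::cor(fa[[which]], fb[[which]], use = "complete.obs")
}
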