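#' Specify a two-age-group cohort
#'
#' Describes the cohort design used throughout the package: a younger and an
#' older group with normally distributed ages (defaults follow a typical
#' lifespan-sampling design: younger 24.2 (SD 3.4) years, older 70.8 (SD 2.7)
#' years) and a per-subject head-motion trait (mean framewise displacement,
#' mm) drawn per group.
#'
#' @param n_young,n_old group sizes (each at least 2).
#' @param young_age_mean,young_age_sd,old_age_mean,old_age_sd age
#'   distributions in years; ages are truncated below at 18 so that the
#'   age-20 reference of the downstream model stays interpretable.
#' @param young_fd_mean,old_fd_mean,fd_sd mean-FD trait distribution (mm);
#'   older adults typically move more.
#' @param seed default seed used by [make_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 30, n_old = 30,
                        young_age_mean = 24.2, young_age_sd = 3.4,
                        old_age_mean = 70.8, old_age_sd = 2.7,
                        young_fd_mean = 0.12, old_fd_mean = 0.18,
                        fd_sd = 0.05, seed = NULL) {
  stop_field(is.numeric(n_young) && n_young >= 2, "n_young", "need at least 2 subjects")
  stop_field(is.numeric(n_old) && n_old >= 2, "n_old", "need at least 2 subjects")
  stop_field(is.numeric(young_age_mean) && young_age_mean > 18, "young_age_mean", "must exceed 18 years")
  stop_field(is.numeric(old_age_mean) && old_age_mean > 18, "old_age_mean", "must exceed 18 years")
  stop_field(is.numeric(young_age_sd) && young_age_sd >= 0, "young_age_sd", "must be >= 0")
  stop_field(is.numeric(old_age_sd) && old_age_sd >= 0, "old_age_sd", "must be >= 0")
  stop_field(is.numeric(young_fd_mean) && young_fd_mean >= 0, "young_fd_mean", "must be >= 0")
  stop_field(is.numeric(old_fd_mean) && old_fd_mean >= 0, "old_fd_mean", "must be >= 0")
  stop_field(is.numeric(fd_sd) && fd_sd >= 0, "fd_sd", "must be >= 0")
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 young_age_mean = young_age_mean, young_age_sd = young_age_sd,
                 old_age_mean = old_age_mean, old_age_sd = old_age_sd,
                 young_fd_mean = young_fd_mean, old_fd_mean = old_fd_mean,
                 fd_sd = fd_sd, seed = seed),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws subject records from a [cohort_spec()]: ages from the two group
#' normals (truncated at > 18 years), sexes balanced within group, and a
#' non-negative mean-FD motion trait per subject.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`. Two calls with the
#'   same spec and seed return identical cohorts.
#' @return A data frame with columns `subject_id`, `age` (years), `group`
#'   (factor, `younger`/`older`), `sex`, `mean_fd` (mm).
#' @export
make_cohort <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  with_seed(seed, {
    n <- spec$n_young + spec$n_old
    age <- c(rnorm_trunc(spec$n_young, spec$young_age_mean, spec$young_age_sd, 18),
             rnorm_trunc(spec$n_old, spec$old_age_mean, spec$old_age_sd, 18))
    fd <- c(rnorm_trunc(spec$n_young, spec$young_fd_mean, spec$fd_sd, 0.005),
            rnorm_trunc(spec$n_old, spec$old_fd_mean, spec$fd_sd, 0.005))
    sex <- c(rep_len(c("M", "F"), spec$n_young), rep_len(c("F", "M"), spec$n_old))
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = age,
      group = factor(rep(c("younger", "older"), c(spec$n_young, spec$n_old)),
                     levels = c("younger", "older")),
      sex = sex,
      mean_fd = fd,
      stringsAsFactors = FALSE
    )
  })
}

#' Distributions for ground-truth edge parameters
#'
#' Each entry is `c(mean, sd)` of a normal from which per-edge parameters
#' are drawn. Defaults are calibrated to resemble Fisher-z functional
#' connectivity in a two-age-group design: baseline FC `alpha_mu` around
#' 0.3 z-units, mean aging slopes `beta_mu` mostly negative (about 69% of
#' edges below zero), between-subject SD around 0.1 z-units at age 20, and
#' log-SD slopes `beta_sigma` mostly positive, so variance tends to grow
#' with age.
#'
#' @param alpha_mu,beta_mu,alpha_sigma,beta_sigma,rho `c(mean, sd)` pairs.
#'   Units: z, z/year, log-z, 1/year, z per mm of mean FD.
#' @return A named list, class `edge_effect_config`.
#' @export
edge_effect_config <- function(alpha_mu = c(0.3, 0.3),
                               beta_mu = c(-0.001, 0.002),
                               alpha_sigma = c(log(0.1), 0.2),
                               beta_sigma = c(0.002, 0.004),
                               rho = c(0, 0.1)) {
  cfg <- list(alpha_mu = alpha_mu, beta_mu = beta_mu, alpha_sigma = alpha_sigma,
              beta_sigma = beta_sigma, rho = rho)
  for (nm in names(cfg)) {
    stop_field(is.numeric(cfg[[nm]]) && length(cfg[[nm]]) == 2L && cfg[[nm]][2L] >= 0,
               nm, "must be c(mean, sd) with sd >= 0")
  }
  structure(cfg, class = "edge_effect_config")
}

#' Sample ground-truth parameters for every connection
#'
#' Draws one parameter vector (alpha_mu, beta_mu, alpha_sigma, beta_sigma,
#' rho) per unordered node pair. Optionally, a per-node latent aging factor
#' can be mixed into the mean slopes so that nodal FC aging effects correlate
#' with other modalities sharing the same latent factor; the marginal
#' distribution of `beta_mu` is preserved (the latent share `coupling^2` of
#' its variance comes from the node factors).
#'
#' @param n_nodes number of nodes (>= 3).
#' @param config an [edge_effect_config()].
#' @param seed integer seed.
#' @param nodal_latent optional numeric vector of length `n_nodes`
#'   (standard-normal scale) of latent nodal aging factors.
#' @param coupling weight in `[0, 1)` of the latent factors in `beta_mu`.
#' @return A data frame with one row per edge: `node_i`, `node_j` (i < j),
#'   `alpha_mu`, `beta_mu`, `alpha_sigma`, `beta_sigma`, `rho`.
#' @export
sample_edge_truth <- function(n_nodes, config = edge_effect_config(), seed = NULL,
                              nodal_latent = NULL, coupling = 0) {
  stop_field(is.numeric(n_nodes) && n_nodes >= 3, "n_nodes", "need at least 3 nodes")
  if (!inherits(config, "edge_effect_config")) config <- do.call(edge_effect_config, config)
  stop_field(coupling >= 0 && coupling < 1, "coupling", "must be in [0, 1)")
  if (!is.null(nodal_latent)) {
    stop_field(length(nodal_latent) == n_nodes, "nodal_latent", "length must equal n_nodes")
  }
  pairs <- edge_pairs(n_nodes)
  m <- nrow(pairs)
  with_seed(seed, {
    draw <- function(par) stats::rnorm(m, config[[par]][1L], config[[par]][2L])
    beta_mu <- if (is.null(nodal_latent) || coupling == 0) {
      draw("beta_mu")
    } else {
      u <- (nodal_latent[pairs[, 1L]] + nodal_latent[pairs[, 2L]]) / sqrt(2)
      config$beta_mu[1L] +
        config$beta_mu[2L] * (coupling * u + sqrt(1 - coupling^2) * stats::rnorm(m))
    }
    data.frame(node_i = pairs[, 1L], node_j = pairs[, 2L],
               alpha_mu = draw("alpha_mu"), beta_mu = beta_mu,
               alpha_sigma = draw("alpha_sigma"), beta_sigma = draw("beta_sigma"),
               rho = draw("rho"))
  })
}

#' Simulate per-subject edge values from the location-scale age model
#'
#' Draws, for each subject and edge, `y = alpha_mu + beta_mu * a + rho * FD
#' + eps`, with `a = age - age_ref` and `eps ~ N(0, exp(alpha_sigma +
#' beta_sigma * a))`. This is the generative counterpart of the model fitted
#' by [fit_map()].
#'
#' @param cohort a cohort data frame from [make_cohort()].
#' @param edge_truth data frame from [sample_edge_truth()].
#' @param seed integer seed.
#' @param age_ref reference age in years (default 20).
#' @return A numeric matrix, subjects in rows (named by `subject_id`),
#'   edges in columns (named `e<i>_<j>`).
#' @export
simulate_edge_values <- function(cohort, edge_truth, seed = NULL, age_ref = 20) {
  stop_field(is.data.frame(cohort) && nrow(cohort) > 0, "cohort", "must be a nonempty data frame")
  a <- cohort$age - age_ref
  fd <- cohort$mean_fd
  n <- nrow(cohort); m <- nrow(edge_truth)
  with_seed(seed, {
    mu <- outer(a, edge_truth$beta_mu) +
      matrix(edge_truth$alpha_mu, n, m, byrow = TRUE) +
      outer(fd, edge_truth$rho)
    sigma <- exp(outer(a, edge_truth$beta_sigma) +
                   matrix(edge_truth$alpha_sigma, n, m, byrow = TRUE))
    y <- mu + sigma * matrix(stats::rnorm(n * m), n, m)
    dimnames(y) <- list(cohort$subject_id,
                        sprintf("e%d_%d", edge_truth$node_i, edge_truth$node_j))
    y
  })
}

#' Distributions for ground-truth nodal parameters (BP and GMD)
#'
#' Same `c(mean, sd)` convention as [edge_effect_config()], for the
#' location-scale model of D1 binding potential and of gray matter density
#' per node. BP defaults put baseline availability near 0.8 with uniformly
#' negative aging slopes (D1 receptors decline in every region); GMD
#' defaults give densities near 0.6 with mild negative mean slopes and a
#' slight tendency for variance to grow with age.
#'
#' @param bp_alpha_mu,bp_beta_mu,bp_alpha_sigma,bp_beta_sigma BP parameters.
#' @param gmd_alpha_mu,gmd_beta_mu,gmd_alpha_sigma,gmd_beta_sigma GMD
#'   parameters.
#' @return A named list, class `node_effect_config`.
#' @export
node_effect_config <- function(bp_alpha_mu = c(0.8, 0.35),
                               bp_beta_mu = c(-0.005, 0.002),
                               bp_alpha_sigma = c(log(0.08), 0.2),
                               bp_beta_sigma = c(0.003, 0.004),
                               gmd_alpha_mu = c(0.6, 0.08),
                               gmd_beta_mu = c(-0.002, 0.001),
                               gmd_alpha_sigma = c(log(0.04), 0.2),
                               gmd_beta_sigma = c(0.001, 0.004)) {
  cfg <- list(bp_alpha_mu = bp_alpha_mu, bp_beta_mu = bp_beta_mu,
              bp_alpha_sigma = bp_alpha_sigma, bp_beta_sigma = bp_beta_sigma,
              gmd_alpha_mu = gmd_alpha_mu, gmd_beta_mu = gmd_beta_mu,
              gmd_alpha_sigma = gmd_alpha_sigma, gmd_beta_sigma = gmd_beta_sigma)
  for (nm in names(cfg)) {
    stop_field(is.numeric(cfg[[nm]]) && length(cfg[[nm]]) == 2L && cfg[[nm]][2L] >= 0,
               nm, "must be c(mean, sd) with sd >= 0")
  }
  structure(cfg, class = "node_effect_config")
}

#' Sample ground-truth nodal parameters for BP and GMD
#'
#' As [sample_edge_truth()] but per node. A latent nodal aging factor can be
#' mixed into `bp_beta_mu` (and, with its own weight, `gmd_beta_mu`) to
#' induce cross-modal correlation of aging effects.
#'
#' @param n_nodes number of nodes.
#' @param config a [node_effect_config()].
#' @param seed integer seed.
#' @param nodal_latent optional standard-normal latent factor per node.
#' @param bp_coupling,gmd_coupling latent weights in `[0, 1)`.
#' @return A data frame with one row per node: `node` plus the eight
#'   parameter columns.
#' @export
sample_node_truth <- function(n_nodes, config = node_effect_config(), seed = NULL,
                              nodal_latent = NULL, bp_coupling = 0, gmd_coupling = 0) {
  stop_field(is.numeric(n_nodes) && n_nodes >= 1, "n_nodes", "need at least 1 node")
  if (!inherits(config, "node_effect_config")) config <- do.call(node_effect_config, config)
  if (!is.null(nodal_latent)) {
    stop_field(length(nodal_latent) == n_nodes, "nodal_latent", "length must equal n_nodes")
  }
  with_seed(seed, {
    draw <- function(par, weight = 0) {
      if (is.null(nodal_latent) || weight == 0) {
        stats::rnorm(n_nodes, config[[par]][1L], config[[par]][2L])
      } else {
        config[[par]][1L] + config[[par]][2L] *
          (weight * nodal_latent + sqrt(1 - weight^2) * stats::rnorm(n_nodes))
      }
    }
    data.frame(node = seq_len(n_nodes),
               bp_alpha_mu = draw("bp_alpha_mu"),
               bp_beta_mu = draw("bp_beta_mu", bp_coupling),
               bp_alpha_sigma = draw("bp_alpha_sigma"),
               bp_beta_sigma = draw("bp_beta_sigma"),
               gmd_alpha_mu = draw("gmd_alpha_mu"),
               gmd_beta_mu = draw("gmd_beta_mu", gmd_coupling),
               gmd_alpha_sigma = draw("gmd_alpha_sigma"),
               gmd_beta_sigma = draw("gmd_beta_sigma"))
  })
}

simulate_nodal_values <- function(cohort, alpha_mu, beta_mu, alpha_sigma, beta_sigma,
                                  seed = NULL, age_ref = 20, node_names = NULL) {
  a <- cohort$age - age_ref
  n <- nrow(cohort); m <- length(alpha_mu)
  with_seed(seed, {
    mu <- outer(a, beta_mu) + matrix(alpha_mu, n, m, byrow = TRUE)
    sigma <- exp(outer(a, beta_sigma) + matrix(alpha_sigma, n, m, byrow = TRUE))
    y <- mu + sigma * matrix(stats::rnorm(n * m), n, m)
    dimnames(y) <- list(cohort$subject_id,
                        if (is.null(node_names)) sprintf("n%d", seq_len(m)) else node_names)
    y
  })
}

#' Simulate per-subject nodal gray matter density
#'
#' Draws a subjects-by-nodes GMD table from the location-scale age model
#' with the `gmd_*` parameters of `node_truth`. No motion term is used
#' (structural estimates carry no FD covariate in the generator).
#'
#' @param cohort cohort data frame.
#' @param node_truth data frame from [sample_node_truth()].
#' @param seed integer seed.
#' @param age_ref reference age (years).
#' @return Numeric matrix, subjects x nodes.
#' @export
simulate_gmd <- function(cohort, node_truth, seed = NULL, age_ref = 20) {
  stop_field(is.data.frame(cohort) && nrow(cohort) > 0, "cohort", "must be a nonempty data frame")
  simulate_nodal_values(cohort, node_truth$gmd_alpha_mu, node_truth$gmd_beta_mu,
                        node_truth$gmd_alpha_sigma, node_truth$gmd_beta_sigma,
                        seed = seed, age_ref = age_ref)
}

#' Simulate per-subject nodal D1 binding potential
#'
#' As [simulate_gmd()] but with the `bp_*` parameters. Values are the true
#' (noise-containing) BP per subject and node; [simulate_tac()] can turn each
#' into a PET time-activity curve with `dvr = 1 + max(bp, 0)`.
#'
#' @inheritParams simulate_gmd
#' @return Numeric matrix, subjects x nodes.
#' @export
simulate_bp <- function(cohort, node_truth, seed = NULL, age_ref = 20) {
  stop_field(is.data.frame(cohort) && nrow(cohort) > 0, "cohort", "must be a nonempty data frame")
  simulate_nodal_values(cohort, node_truth$bp_alpha_mu, node_truth$bp_beta_mu,
                        node_truth$bp_alpha_sigma, node_truth$bp_beta_sigma,
                        seed = seed, age_ref = age_ref)
}
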