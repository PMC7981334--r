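#' Configuration for a full synthetic study run
#'
#' Bundles every knob of the end-to-end synthetic analysis: cohort design,
#' number of nodes, ground-truth effect distributions, cross-modal coupling
#' of nodal aging effects, model priors and optimizer settings, Logan
#' window, connection-removal fractions, and one global seed from which all
#' stage seeds are derived.
#'
#' @param n_nodes connectome size (default 60 — large enough for stable
#'   similarity structure, small enough for interactive runs).
#' @param cohort a [cohort_spec()].
#' @param edge_config an [edge_effect_config()].
#' @param node_config a [node_effect_config()].
#' @param fc_coupling,bp_coupling,gmd_coupling weights of the shared latent
#'   nodal aging factor in edge `beta_mu`, BP `beta_mu` and GMD `beta_mu`.
#' @param priors an [age_model_priors()].
#' @param settings a [fit_settings()].
#' @param logan_window Logan window, minutes.
#' @param tac_noise_sd PET frame noise as a fraction of the peak reference
#'   value.
#' @param removal_fractions connection-removal fractions in `[0, 1)`.
#' @param age_ref reference age, years.
#' @param seed global integer seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_nodes = 60, cohort = cohort_spec(),
                         edge_config = edge_effect_config(),
                         node_config = node_effect_config(),
                         fc_coupling = 0.6, bp_coupling = 0.6,
                         gmd_coupling = 0.3,
                         priors = age_model_priors(),
                         settings = fit_settings(),
                         logan_window = c(18, 55), tac_noise_sd = 0.02,
                         removal_fractions = c(0, 0.1, 0.2, 0.3),
                         age_ref = 20, seed = 1) {
  stop_field(is.numeric(n_nodes) && n_nodes >= 3, "n_nodes", "need at least 3 nodes")
  stop_field(inherits(cohort, "cohort_spec"), "cohort", "must be a cohort_spec")
  stop_field(all(removal_fractions >= 0 & removal_fractions < 1),
             "removal_fractions", "must lie in [0, 1)")
  structure(list(n_nodes = as.integer(n_nodes), cohort = cohort,
                 edge_config = edge_config, node_config = node_config,
                 fc_coupling = fc_coupling, bp_coupling = bp_coupling,
                 gmd_coupling = gmd_coupling, priors = priors,
                 settings = settings, logan_window = logan_window,
                 tac_noise_sd = tac_noise_sd,
                 removal_fractions = removal_fractions,
                 age_ref = age_ref, seed = as.integer(seed)),
            class = "study_config")
}

obj_checksum <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full synthetic study
#'
#' Executes the pipeline stages in dependency order: cohort and ground-truth
#' generation, FC simulation from the generative age model, per-edge MAP
#' fitting, connectome similarity / MDS / connection-removal analysis, PET
#' simulation with Logan quantification and nodal BP fits, GMD simulation
#' and fits, and cross-modal association. Every stage draws from a seed
#' derived deterministically from the global seed and the stage name, so two
#' runs with the same config are identical.
#'
#' @param config a [study_config()].
#' @param stages subset of
#'   `c("simulate", "fit_fc", "similarity", "removal", "pet", "gmd",
#'   "crossmodal")`; stages required by a requested stage are always run.
#' @param verbose print stage progress.
#' @return A list of class `study_run` with elements per stage plus
#'   `manifest` (config, seed, per-stage result checksums).
#' @export
run_synthetic_study <- function(config = study_config(),
                                stages = c("simulate", "fit_fc", "similarity",
                                           "removal", "pet", "gmd", "crossmodal"),
                                verbose = FALSE) {
  all_stages <- c("simulate", "fit_fc", "similarity", "removal", "pet", "gmd",
                  "crossmodal")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(simulate = character(), fit_fc = "simulate",
               similarity = "simulate", removal = c("simulate", "fit_fc"),
               pet = "simulate", gmd = "simulate",
               crossmodal = c("fit_fc", "pet", "gmd"))
  needed <- stages
  repeat {
    more <- unique(unlist(deps[needed]))
    if (all(more %in% needed)) break
    needed <- union(needed, more)
  }
  run <- intersect(all_stages, needed)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list(config = config)
  checks <- list()

  if ("simulate" %in% run) {
    say("stage simulate: cohort of %d + %d subjects, %d nodes",
        config$cohort$n_young, config$cohort$n_old, config$n_nodes)
    cohort <- make_cohort(config$cohort, seed = stage_seed(config$seed, "cohort"))
    latent <- with_seed(stage_seed(config$seed, "latent"),
                        stats::rnorm(config$n_nodes))
    edge_truth <- sample_edge_truth(config$n_nodes, config$edge_config,
                                    seed = stage_seed(config$seed, "edge_truth"),
                                    nodal_latent = latent,
                                    coupling = config$fc_coupling)
    node_truth <- sample_node_truth(config$n_nodes, config$node_config,
                                    seed = stage_seed(config$seed, "node_truth"),
                                    nodal_latent = latent,
                                    bp_coupling = config$bp_coupling,
                                    gmd_coupling = config$gmd_coupling)
    edge_values <- simulate_edge_values(cohort, edge_truth,
                                        seed = stage_seed(config$seed, "edges"),
                                        age_ref = config$age_ref)
    out$cohort <- cohort
    out$truth <- list(latent = latent, edges = edge_truth, nodes = node_truth)
    out$edge_values <- edge_values
    checks$simulate <- obj_checksum(list(cohort, edge_truth, node_truth, edge_values))
  }

  if ("fit_fc" %in% run) {
    say("stage fit_fc: %d edges x %d subjects", ncol(out$edge_values), nrow(out$cohort))
    out$fits_fc <- fit_all(out$edge_values, out$cohort$age, out$cohort$mean_fd,
                           priors = config$priors, settings = config$settings,
                           age_ref = config$age_ref)
    checks$fit_fc <- obj_checksum(out$fits_fc$fits)
  }

  if ("similarity" %in% run) {
    say("stage similarity")
    s <- similarity_matrix(out$edge_values, out$cohort)
    out$similarity <- list(matrix = s,
                           summary = group_similarity_summary(s),
                           mds = classical_mds(s, n_dims = 2))
    checks$similarity <- obj_checksum(out$similarity$matrix)
  }

  if ("removal" %in% run) {
    say("stage removal: fractions %s", paste(config$removal_fractions, collapse = ", "))
    f <- out$fits_fc$fits
    out$removal <- list(
      by_beta_mu = connection_removal_curve(out$edge_values, f$beta_mu,
                                            config$removal_fractions, out$cohort),
      by_beta_sigma = connection_removal_curve(out$edge_values, f$beta_sigma,
                                               config$removal_fractions, out$cohort),
      random = connection_removal_curve(out$edge_values, "random",
                                        config$removal_fractions, out$cohort,
                                        seed = stage_seed(config$seed, "removal"))
    )
    checks$removal <- obj_checksum(out$removal)
  }

  if ("pet" %in% run) {
    say("stage pet: Logan DVR for %d subjects x %d nodes",
        nrow(out$cohort), config$n_nodes)
    bp_true <- simulate_bp(out$cohort, out$truth$nodes,
                           seed = stage_seed(config$seed, "bp"),
                           age_ref = config$age_ref)
    sched <- pet_frame_schedule()
    bp_est <- bp_true
    base_seed <- stage_seed(config$seed, "tac")
    for (s_i in seq_len(nrow(bp_true))) {
      for (n_i in seq_len(ncol(bp_true))) {
        curves <- simulate_tac(1 + max(bp_true[s_i, n_i], 0),
                               schedule = sched,
                               noise_sd = config$tac_noise_sd,
                               seed = base_seed + s_i * 1000L + n_i)
        bp_est[s_i, n_i] <- logan_dvr(curves$target, curves$reference,
                                      window = config$logan_window)$bp
      }
    }
    out$bp_true <- bp_true
    out$bp_values <- bp_est
    out$fits_bp <- fit_all(bp_est, out$cohort$age, out$cohort$mean_fd,
                           priors = config$priors, settings = config$settings,
                           age_ref = config$age_ref)
    checks$pet <- obj_checksum(list(bp_est, out$fits_bp$fits))
  }

  if ("gmd" %in% run) {
    say("stage gmd")
    gmd <- simulate_gmd(out$cohort, out$truth$nodes,
                        seed = stage_seed(config$seed, "gmd"),
                        age_ref = config$age_ref)
    out$gmd_values <- gmd
    out$fits_gmd <- fit_all(gmd, out$cohort$age, out$cohort$mean_fd,
                            priors = config$priors, settings = config$settings,
                            age_ref = config$age_ref)
    checks$gmd <- obj_checksum(list(gmd, out$fits_gmd$fits))
  }

  if ("crossmodal" %in% run) {
    say("stage crossmodal")
    nodal_fc <- nodal_beta_table(edge_fits_with_nodes(out$fits_fc))
    fc_mu <- stats::setNames(nodal_fc$avg_beta_mu, nodal_fc$node)
    fc_sd <- stats::setNames(nodal_fc$avg_beta_sigma, nodal_fc$node)
    bp_mu <- stats::setNames(out$fits_bp$fits$beta_mu,
                             sub("^n", "", out$fits_bp$fits$feature_id))
    bp_sd <- stats::setNames(out$fits_bp$fits$beta_sigma, names(bp_mu))
    gmd_mu <- stats::setNames(out$fits_gmd$fits$beta_mu,
                              sub("^n", "", out$fits_gmd$fits$feature_id))
    gmd_sd <- stats::setNames(out$fits_gmd$fits$beta_sigma, names(gmd_mu))
    preds <- data.frame(bp_beta_mu = bp_mu[names(fc_mu)],
                        gmd_beta_mu = gmd_mu[names(fc_mu)])
    out$crossmodal <- list(
      nodal_fc = nodal_fc,
      cor_mu_fc_bp = nodal_correlation(fc_mu, bp_mu),
      cor_mu_fc_gmd = nodal_correlation(fc_mu, gmd_mu),
      cor_sigma_fc_bp = nodal_correlation(fc_sd, bp_sd),
      cor_sigma_fc_gmd = nodal_correlation(fc_sd, gmd_sd),
      regression = joint_regression(fc_mu, preds)
    )
    checks$crossmodal <- obj_checksum(out$crossmodal)
  }

  out$manifest <- list(seed = config$seed,
                       stages = run,
                       config_checksum = obj_checksum(config),
                       stage_checksums = unlist(checks),
                       package_version = as.character(utils::packageVersion("fcaging")),
                       timestamp = format(Sys.time(), tz = "UTC"))
  class(out) <- "study_run"
  out
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("<study_run> seed %d, stages: %s\n", x$manifest$seed,
              paste(x$manifest$stages, collapse = ", ")))
  invisible(x)
}

#' Validate study inputs against their type contracts
#'
#' Checks in-memory inputs (subject table, motion traces, ROI series, TACs)
#' against the invariants of their types and returns a report of violations
#' without aborting — an empty report means the inputs are clean.
#'
#' @param subjects optional subject data frame (`subject_id`, `age`,
#'   `group`, `sex`, `mean_fd`).
#' @param motion optional volumes x 6 motion matrix, or list thereof.
#' @param series optional volumes x ROIs matrix, or list thereof (checked
#'   against `motion` row counts when both given).
#' @param tacs optional list of [tac()] objects.
#' @return Data frame with columns `input` and `problem`; zero rows when
#'   everything validates.
#' @export
validate_inputs <- function(subjects = NULL, motion = NULL, series = NULL,
                            tacs = NULL) {
  problems <- list()
  note <- function(input, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(input = input, problem = problem)
  }
  if (!is.null(subjects)) {
    need <- c("subject_id", "age", "group", "sex", "mean_fd")
    miss <- setdiff(need, names(subjects))
    if (length(miss)) note("subjects", paste("missing columns:", paste(miss, collapse = ", ")))
    if ("age" %in% names(subjects) && any(subjects$age <= 0, na.rm = TRUE)) {
      note("subjects", "ages must be positive")
    }
    if ("mean_fd" %in% names(subjects) && any(subjects$mean_fd < 0, na.rm = TRUE)) {
      note("subjects", "mean_fd must be non-negative")
    }
    if ("subject_id" %in% names(subjects) && anyDuplicated(subjects$subject_id)) {
      note("subjects", "duplicated subject ids")
    }
  }
  as_list <- function(x) if (is.list(x) && !is.data.frame(x)) x else list(x)
  if (!is.null(motion)) {
    for (i in seq_along(as_list(motion))) {
      m <- as.matrix(as_list(motion)[[i]])
      if (ncol(m) != 6L) note(sprintf("motion[%d]", i),
                              sprintf("has %d columns, expected 6", ncol(m)))
      if (any(!is.finite(m))) note(sprintf("motion[%d]", i), "non-finite values")
    }
  }
  if (!is.null(series)) {
    ser <- as_list(series)
    mot <- if (!is.null(motion)) as_list(motion) else NULL
    for (i in seq_along(ser)) {
      s <- as.matrix(ser[[i]])
      if (any(!is.finite(s))) note(sprintf("series[%d]", i), "non-finite values")
      if (!is.null(mot) && i <= length(mot) &&
          nrow(s) != nrow(as.matrix(mot[[i]]))) {
        note(sprintf("series[%d]", i), "volume count differs from motion trace")
      }
    }
  }
  if (!is.null(tacs)) {
    for (i in seq_along(tacs)) {
      t_i <- tacs[[i]]
      if (!inherits(t_i, "tac")) {
        note(sprintf("tacs[%d]", i), "not a tac object")
      } else if (any(t_i$activity < 0)) {
        note(sprintf("tacs[%d]", i), "negative activity")
      }
    }
  }
  if (length(problems)) do.call(rbind, problems) else
    data.frame(input = character(), problem = character())
}
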