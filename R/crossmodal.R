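#' Attach node indices to an edge fit table
#'
#' Edge features produced by [simulate_edge_values()] / [fit_all()] are
#' named `e<i>_<j>`; this parses the node pair back out so edge-level
#' aging effects can be aggregated per node.
#'
#' @param fits an `aging_effect_table` or its `fits` data frame with
#'   `feature_id` of the form `e<i>_<j>`.
#' @return The fits data frame with integer `node_i` and `node_j` columns.
#' @export
edge_fits_with_nodes <- function(fits) {
  f <- if (inherits(fits, "aging_effect_table")) fits$fits else fits
  m <- regmatches(f$feature_id, regexec("^e([0-9]+)_([0-9]+)$", f$feature_id))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("feature ids are not of the form e<i>_<j>; supply node columns directly",
         call. = FALSE)
  }
  f$node_i <- as.integer(vapply(m, `[`, character(1), 2L))
  f$node_j <- as.integer(vapply(m, `[`, character(1), 3L))
  f
}

#' Average nodal aging effect
#'
#' Arithmetic mean of an edge-level parameter over all edges incident to a
#' node — the nodal summary of edge-wise aging effects.
#'
#' @param edge_table data frame with `node_i`, `node_j` and the parameter
#'   column (e.g. from [edge_fits_with_nodes()] or [sample_edge_truth()]).
#' @param node node index.
#' @param which column to average, `"beta_mu"` or `"beta_sigma"`.
#' @return Scalar mean over the incident edges.
#' @export
average_nodal_beta <- function(edge_table, node, which = c("beta_mu", "beta_sigma")) {
  which <- match.arg(which)
  hit <- edge_table$node_i == node | edge_table$node_j == node
  if (!any(hit)) stop(sprintf("node %s has no incident edges", node), call. = FALSE)
  mean(edge_table[[which]][hit])
}

#' Average nodal aging effects for every node
#'
#' @inheritParams average_nodal_beta
#' @param nodes nodes to summarize (default: all nodes present).
#' @return Data frame with `node`, `avg_beta_mu`, `avg_beta_sigma`, and
#'   `degree` (number of incident edges).
#' @export
nodal_beta_table <- function(edge_table, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edge_table$node_i, edge_table$node_j)))
  both <- c(edge_table$node_i, edge_table$node_j)
  bm <- rep(edge_table$beta_mu, 2L)
  bs <- rep(edge_table$beta_sigma, 2L)
  data.frame(
    node = nodes,
    avg_beta_mu = vapply(nodes, function(k) mean(bm[both == k]), numeric(1)),
    avg_beta_sigma = vapply(nodes, function(k) mean(bs[both == k]), numeric(1)),
    degree = vapply(nodes, function(k) sum(both == k), numeric(1))
  )
}

#' Assign each ROI to a region or network by highest score
#'
#' Region mode takes the arg-max of the supplied membership probabilities.
#' Network mode first multiplies each ROI's mean map value by the ROI size
#' (voxels), producing a score per network-ROI combination, then takes the
#' arg-max. Exact ties go to the first (lowest-index) label with a warning;
#' all-zero score rows are flagged with `NA`.
#'
#' @param scores ROIs x labels numeric matrix (or data frame) of membership
#'   probabilities (region mode) or mean map values (network mode).
#' @param mode `"region"` or `"network"`.
#' @param roi_sizes ROI sizes in voxels (required in network mode).
#' @return Character vector of assigned labels, named by ROI when `scores`
#'   has row names.
#' @export
assign_partition <- function(scores, mode = c("region", "network"), roi_sizes = NULL) {
  mode <- match.arg(mode)
  s <- as.matrix(scores)
  if (any(!is.finite(s))) stop("partition scores must be finite", call. = FALSE)
  if (mode == "network") {
    stop_field(!is.null(roi_sizes) && length(roi_sizes) == nrow(s), "roi_sizes",
               "network mode needs one ROI size per row")
    s <- s * roi_sizes
  }
  labels <- colnames(s)
  if (is.null(labels)) labels <- sprintf("label_%d", seq_len(ncol(s)))
  pick <- apply(s, 1L, function(row) {
    if (all(row == 0)) return(NA_integer_)
    which.max(row)  # which.max already takes the first maximum on ties
  })
  n_tie <- sum(apply(s, 1L, function(row) sum(row == max(row)) > 1L & !all(row == 0)))
  if (n_tie > 0) warning(sprintf("%d ROI(s) had tied scores; first label used", n_tie))
  if (anyNA(pick)) warning(sprintf("%d ROI(s) had all-zero scores; assigned NA", sum(is.na(pick))))
  out <- labels[pick]
  names(out) <- rownames(s)
  out
}

#' Correlation between nodal aging effects of two modalities
#'
#' Pearson correlation (with two-sided p value) between per-ROI aging-effect
#' series, over the ROIs shared by both series after removing `exclude`
#' (e.g. high-leverage regions for a sensitivity check).
#'
#' @param x,y named numeric vectors (names are ROI ids); unnamed vectors are
#'   matched by position.
#' @param exclude ROI ids (or indices, for unnamed input) to drop.
#' @param min_n minimum number of shared ROIs (default 10).
#' @return List with `r`, `p`, `n`.
#' @export
nodal_correlation <- function(x, y, exclude = NULL, min_n = 10) {
  if (is.null(names(x)) || is.null(names(y))) {
    stop_field(length(x) == length(y), "y", "unnamed series must have equal length")
    names(x) <- names(y) <- as.character(seq_along(x))
  }
  shared <- setdiff(intersect(names(x), names(y)), as.character(exclude))
  if (length(shared) < min_n) {
    stop(sprintf("only %d shared ROIs after exclusion (need >= %d)",
                 length(shared), min_n), call. = FALSE)
  }
  xv <- x[shared]; yv <- y[shared]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Joint regression of FC aging effects on BP and GMD aging effects
#'
#' Ordinary least squares of the (z-scored) average nodal FC `beta_mu` on
#' the (z-scored) BP and GMD `beta_mu` values, testing whether the two
#' modalities account for independent portions of the variance. Both
#' standardized and raw-scale coefficients are reported.
#'
#' @param response named numeric vector of average nodal FC effects.
#' @param predictors data frame or matrix of per-ROI predictor columns
#'   (same ROIs as `response`; matched by row name when available).
#' @param min_n minimum number of complete ROIs.
#' @return List with `standardized` (coefficient, p per predictor),
#'   `raw` (unstandardized coefficients incl. intercept), `r_squared`, `n`.
#' @export
joint_regression <- function(response, predictors, min_n = 10) {
  X <- as.matrix(predictors)
  stop_field(length(response) == nrow(X), "predictors",
             "row count must match the response")
  ok <- stats::complete.cases(cbind(response, X))
  yv <- response[ok]; Xv <- X[ok, , drop = FALSE]
  if (sum(ok) < min_n) {
    stop(sprintf("only %d complete ROIs (need >= %d)", sum(ok), min_n), call. = FALSE)
  }
  if (ncol(Xv) >= 2L) {
    cc <- stats::cor(Xv)
    if (any(abs(cc[upper.tri(cc)]) > 0.999)) {
      stop("predictors are collinear (|r| > 0.999)", call. = FALSE)
    }
  }
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  yz <- zs(yv)
  Xz <- apply(Xv, 2L, zs)
  fit_z <- stats::lm(yz ~ Xz)
  sm <- summary(fit_z)$coefficients
  std <- data.frame(predictor = colnames(Xv),
                    coefficient = sm[-1L, "Estimate"],
                    p = sm[-1L, "Pr(>|t|)"], row.names = NULL)
  fit_raw <- stats::lm(yv ~ Xv)
  raw <- stats::coef(fit_raw)
  names(raw) <- c("(Intercept)", colnames(Xv))
  list(standardized = std, raw = raw,
       r_squared = summary(fit_z)$r.squared, n = sum(ok))
}

#' Reorder a connection matrix into partition blocks
#'
#' Permutes rows and columns so nodes with the same partition label are
#' contiguous (label order preserved as given by `factor` levels, ties by
#' node index); the contents are unchanged.
#'
#' @param mat square symmetric matrix over nodes.
#' @param labels partition label per node.
#' @return List with `matrix` (reordered), `order` (permutation applied),
#'   and `boundaries` (last row index of each block, named by label).
#' @export
arrange_by_partition <- function(mat, labels) {
  stop_field(length(labels) == nrow(mat), "labels", "must cover all nodes")
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  ord <- order(f, seq_along(labels))
  out <- mat[ord, ord, drop = FALSE]
  counts <- table(f)
  boundaries <- cumsum(as.integer(counts))
  names(boundaries) <- names(counts)
  list(matrix = out, order = ord, boundaries = boundaries)
}
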