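#' Stack connectomes into a subjects-by-edges matrix
#'
#' @param connectomes list of [connectome()] objects with identical ROI
#'   label lists.
#' @return Matrix of upper-triangle Fisher-z values, one row per subject.
#' @export
connectome_edge_matrix <- function(connectomes) {
  stopifnot(length(connectomes) >= 1L)
  labels <- connectomes[[1L]]$labels
  for (cn in connectomes) {
    if (!identical(cn$labels, labels)) {
      stop("connectomes have mismatching ROI label lists", call. = FALSE)
    }
  }
  out <- t(vapply(connectomes, upper_tri_values,
                  numeric(choose(length(labels), 2))))
  rownames(out) <- vapply(connectomes, function(cn) cn$subject_id, character(1))
  out
}

#' Similarity between two functional connectomes
#'
#' Pearson correlation between the `n(n-1)/2` upper-triangle Fisher-z values
#' of the two connectomes (diagonal excluded).
#'
#' @param c1,c2 [connectome()] objects over the same ROI label list.
#' @return A correlation in `[-1, 1]`.
#' @export
connectome_similarity <- function(c1, c2) {
  if (!identical(c1$labels, c2$labels)) {
    stop("connectomes have mismatching ROI label lists", call. = FALSE)
  }
  stats::cor(upper_tri_values(c1), upper_tri_values(c2))
}

#' Pairwise similarity matrix over a cohort, ordered by age
#'
#' @param connectomes list of [connectome()] objects (>= 2), or a
#'   subjects-by-edges matrix with subject ids as row names.
#' @param subjects cohort data frame with `subject_id` and `age`; rows are
#'   matched to the connectomes and the output is sorted by ascending age.
#' @return A symmetric similarity matrix (class `similarity_matrix`) with
#'   unit diagonal, subject ids as dimnames, and attributes `age` and
#'   `group` (when available) in matrix order.
#' @export
similarity_matrix <- function(connectomes, subjects) {
  edges <- if (is.matrix(connectomes)) connectomes else connectome_edge_matrix(connectomes)
  stop_field(nrow(edges) >= 2L, "connectomes", "need at least 2 subjects")
  idx <- match(rownames(edges), subjects$subject_id)
  if (any(is.na(idx))) stop("subjects table is missing some connectome subjects", call. = FALSE)
  ord <- order(subjects$age[idx])
  edges <- edges[ord, , drop = FALSE]
  s <- stats::cor(t(edges))
  diag(s) <- 1
  dimnames(s) <- list(rownames(edges), rownames(edges))
  attr(s, "age") <- subjects$age[idx][ord]
  if (!is.null(subjects$group)) attr(s, "group") <- subjects$group[idx][ord]
  class(s) <- c("similarity_matrix", class(s))
  s
}

pair_values <- function(s, rows, cols = rows) {
  if (identical(rows, cols)) {
    m <- s[rows, rows, drop = FALSE]
    m[upper.tri(m)]
  } else {
    as.vector(s[rows, cols, drop = FALSE])
  }
}

#' Group-level similarity summary
#'
#' Means of the pairwise similarities within the younger group, within the
#' older group and between groups (diagonal excluded), the
#' younger-younger minus older-older and older-older minus younger-older
#' differences, and Welch two-sample t tests on the corresponding
#' pair-similarity sets. Note the tests treat pair similarities as
#' independent observations, which they are not (each subject contributes
#' to many pairs); they reproduce a common descriptive procedure and should
#' be read as such.
#'
#' @param s a [similarity_matrix()].
#' @param group group labels in matrix order (defaults to the matrix's
#'   `group` attribute); must have levels `younger` and `older`.
#' @return A list of class `group_similarity_summary`: `mean_yy`,
#'   `mean_oo`, `mean_yo`, `diff_yy_oo`, `diff_oo_yo`, pair counts and the
#'   t statistics and p values of both tests.
#' @export
group_similarity_summary <- function(s, group = attr(s, "group")) {
  if (is.null(group)) stop("group labels are required", call. = FALSE)
  stop_field(length(group) == nrow(s), "group", "length must match the similarity matrix")
  young <- which(group == "younger")
  old <- which(group == "older")
  if (length(young) < 2L || length(old) < 2L) {
    stop("both groups need at least 2 members for within-group means", call. = FALSE)
  }
  yy <- pair_values(s, young)
  oo <- pair_values(s, old)
  yo <- pair_values(s, young, old)
  safe_t <- function(a, b) {
    tryCatch(stats::t.test(a, b),
             error = function(e) list(statistic = c(t = NA_real_),
                                      p.value = NA_real_))
  }
  t_yy_oo <- safe_t(yy, oo)
  t_oo_yo <- safe_t(oo, yo)
  structure(list(
    mean_yy = mean(yy), mean_oo = mean(oo), mean_yo = mean(yo),
    diff_yy_oo = mean(yy) - mean(oo), diff_oo_yo = mean(oo) - mean(yo),
    n_yy = length(yy), n_oo = length(oo), n_yo = length(yo),
    t_yy_oo = unname(t_yy_oo$statistic), p_yy_oo = t_yy_oo$p.value,
    t_oo_yo = unname(t_oo_yo$statistic), p_oo_yo = t_oo_yo$p.value
  ), class = "group_similarity_summary")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities, eigendecomposes, and returns
#' the top `n_dims` eigenvectors scaled by the square root of their
#' eigenvalues. Negative eigenvalues are truncated to 0; if fewer than
#' `n_dims` positive eigenvalues exist, the remaining coordinates are zero
#' and a warning is emitted.
#'
#' @param x a [similarity_matrix()] (converted to dissimilarities) or a
#'   dissimilarity matrix.
#' @param n_dims embedding dimension (default 2).
#' @param input `"similarity"` (dissimilarity taken as `1 - x`, the minimal
#'   monotone transform) or `"dissimilarity"`.
#' @return Coordinates matrix (subjects x `n_dims`) with attribute
#'   `eigenvalues`.
#' @export
classical_mds <- function(x, n_dims = 2, input = c("similarity", "dissimilarity")) {
  input <- match.arg(input)
  d <- as.matrix(x)
  if (input == "similarity") d <- 1 - d
  diag(d) <- 0
  n <- nrow(d)
  stop_field(n >= 3L, "x", "need at least 3 subjects")
  d2 <- d^2
  # B = -0.5 * J D^2 J with J = I - 11'/n
  b <- -0.5 * (d2 - outer(rowMeans(d2), rep(1, n)) -
                 outer(rep(1, n), colMeans(d2)) + mean(d2))
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- sum(eig$values > 1e-12 * max(abs(eig$values), 1))
  if (pos < n_dims) {
    warning(sprintf("only %d positive eigenvalue(s); remaining coordinates are zero", pos))
  }
  k <- min(n_dims, n)
  lambda <- pmax(eig$values[seq_len(k)], 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lambda), k)
  if (n_dims > n) coords <- cbind(coords, matrix(0, n, n_dims - n))
  rownames(coords) <- rownames(d)
  colnames(coords) <- sprintf("dim%d", seq_len(ncol(coords)))
  attr(coords, "eigenvalues") <- eig$values
  coords
}

#' Connection-removal similarity curves
#'
#' Quantifies how much each connection contributes to group similarity
#' structure: for each removal fraction `f`, the top `f` fraction of edges
#' by `|ranking|` is removed (ties broken by edge index) and the group
#' similarity summary is recomputed on the remaining edges.
#'
#' @param edges subjects-by-edges matrix (e.g. from
#'   [connectome_edge_matrix()] or [simulate_edge_values()]).
#' @param ranking per-edge ranking values (e.g. fitted `beta_mu`); length
#'   must equal the edge count. Use `"random"` with a `seed` for a random
#'   removal baseline.
#' @param fractions removal fractions in `[0, 1)`.
#' @param subjects cohort data frame (`subject_id`, `age`, `group`).
#' @param seed seed for the random baseline ranking.
#' @return Data frame with one row per fraction: `fraction`, `n_removed`,
#'   `mean_yy`, `mean_oo`, `mean_yo`, `diff_yy_oo`, `diff_yy_yo`.
#' @export
connection_removal_curve <- function(edges, ranking, fractions, subjects, seed = NULL) {
  m <- ncol(edges)
  if (identical(ranking, "random")) {
    ranking <- with_seed(seed, stats::runif(m))
  }
  stop_field(length(ranking) == m, "ranking", "must cover all edges")
  stop_field(all(fractions >= 0) && all(fractions < 1), "fractions",
             "must lie in [0, 1): removing every edge leaves nothing to correlate")
  ord <- order(-abs(ranking), seq_len(m))
  rows <- lapply(fractions, function(f) {
    n_remove <- floor(f * m)
    keep_edges <- if (n_remove > 0) setdiff(seq_len(m), ord[seq_len(n_remove)]) else seq_len(m)
    s <- similarity_matrix(edges[, keep_edges, drop = FALSE], subjects)
    g <- group_similarity_summary(s)
    data.frame(fraction = f, n_removed = n_remove,
               mean_yy = g$mean_yy, mean_oo = g$mean_oo, mean_yo = g$mean_yo,
               diff_yy_oo = g$diff_yy_oo, diff_yy_yo = g$mean_yy - g$mean_yo)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
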