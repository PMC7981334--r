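#' Construct a functional connectome object
#'
#' A connectome stores the Fisher-z functional connectivity of one subject
#' in one experiment as a symmetric matrix over retained ROIs. The diagonal
#' is stored as 0 and excluded from every downstream analysis.
#'
#' @param z square numeric matrix of Fisher-z values; must be symmetric
#'   (small asymmetries from floating-point round-off are symmetrized
#'   exactly) with finite off-diagonal entries.
#' @param labels ROI labels; defaults to the matrix column names or
#'   `roi_1 ... roi_n`.
#' @param subject_id subject identifier.
#' @param meta named list of metadata (e.g. `n_volumes_used`,
#'   `mean_fd_after_scrub`, `gsr`, experiment tag).
#' @return An object of class `connectome`.
#' @export
connectome <- function(z, labels = NULL, subject_id = NA_character_, meta = list()) {
  if (!is.matrix(z) || nrow(z) != ncol(z)) stop("`z` must be a square matrix", call. = FALSE)
  if (max(abs(z - t(z))) > 1e-8) stop("`z` must be symmetric", call. = FALSE)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  if (any(!is.finite(z))) stop("connectome entries must be finite", call. = FALSE)
  if (is.null(labels)) labels <- colnames(z)
  if (is.null(labels)) labels <- sprintf("roi_%d", seq_len(ncol(z)))
  if (length(labels) != ncol(z)) stop("`labels` length must match matrix size", call. = FALSE)
  dimnames(z) <- list(labels, labels)
  structure(list(z = z, labels = as.character(labels),
                 subject_id = subject_id, meta = meta),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s: %d ROIs, %d connections\n",
              x$subject_id, length(x$labels), choose(length(x$labels), 2)))
  invisible(x)
}

#' Assemble a connectome from an edge-value vector
#'
#' Inverse of [upper_tri_values()]: places `n(n-1)/2` edge values (in the
#' canonical [edge_pairs()] order) into a symmetric matrix with zero
#' diagonal.
#'
#' @param values edge values, length `n_nodes * (n_nodes - 1) / 2`.
#' @param n_nodes number of nodes.
#' @inheritParams connectome
#' @return A `connectome`.
#' @export
connectome_from_edges <- function(values, n_nodes, labels = NULL,
                                  subject_id = NA_character_, meta = list()) {
  pairs <- edge_pairs(n_nodes)
  if (length(values) != nrow(pairs)) {
    stop(sprintf("expected %d edge values for %d nodes, got %d",
                 nrow(pairs), n_nodes, length(values)), call. = FALSE)
  }
  z <- matrix(0, n_nodes, n_nodes)
  z[pairs] <- values
  z[pairs[, c(2L, 1L)]] <- values
  connectome(z, labels = labels, subject_id = subject_id, meta = meta)
}

#' Extract the upper-triangle edge values of a connectome
#'
#' Returns the `n(n-1)/2` off-diagonal values in the canonical
#' [edge_pairs()] order (diagonal excluded).
#'
#' @param x a `connectome` or a symmetric matrix.
#' @return Numeric vector of edge values.
#' @export
upper_tri_values <- function(x) {
  z <- if (inherits(x, "connectome")) x$z else x
  z[edge_pairs(ncol(z))]
}
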