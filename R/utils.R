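#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so that seeded generators do not disturb
#' the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-local seed from a global seed and a stage name
#'
#' Deterministic mapping used by the workbench so that each pipeline stage
#' has its own reproducible stream. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483629) + 1L
}

stop_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Upper-triangle index pairs of an n-node graph
#'
#' @param n_nodes number of nodes.
#' @return A two-column integer matrix (node_i < node_j), one row per
#'   unordered pair, n(n-1)/2 rows in row-major (by node_i) order.
#' @export
edge_pairs <- function(n_nodes) {
  stop_field(is.numeric(n_nodes) && n_nodes >= 2, "n_nodes", "need at least 2 nodes")
  n <- as.integer(n_nodes)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(node_i = i, node_j = j)
}

#' Fisher z-transform of a correlation, clamped away from +/- 1
#'
#' @param r correlation value(s).
#' @param clamp clamp bound; `r` is limited to `[-(1-clamp), 1-clamp]`
#'   before `atanh` so the result stays finite.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r, clamp = 1e-7) {
  atanh(pmin(pmax(r, -(1 - clamp)), 1 - clamp))
}

# trapezoidal cumulative integral of (x, y) samples, returned at each x
cumtrapz1 <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-n] + y[-1L]) / 2))
}
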