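#' Read and write the package's tabular interchange formats
#'
#' Plain TSV with a header row; subject tables use columns `subject_id`,
#' `age`, `group`, `sex`, `mean_fd`; edge ground truth uses `node_i`,
#' `node_j`, `alpha_mu`, `beta_mu`, `alpha_sigma`, `beta_sigma`, `rho`;
#' fit tables use the columns produced by [fit_all()].
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_table_tsv` returns a data frame; writers return `path`
#'   invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a connectome as a square TSV
#'
#' The matrix is written with ROI labels as header row and first column;
#' metadata (subject id, volumes used, mean FD, GSR flag) goes to a sidecar
#' `<path>.meta.tsv` as key-value pairs.
#'
#' @param cn a [connectome()].
#' @param path file path for the matrix TSV.
#' @return `read_connectome` returns a [connectome()]; the writer returns
#'   `path` invisibly.
#' @export
write_connectome <- function(cn, path) {
  stopifnot(inherits(cn, "connectome"))
  utils::write.table(cn$z, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  meta <- c(list(subject_id = cn$subject_id), cn$meta)
  kv <- data.frame(key = names(meta),
                   value = vapply(meta, function(v) as.character(v)[1], character(1)))
  utils::write.table(kv, paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  meta_path <- paste0(path, ".meta.tsv")
  subject_id <- NA_character_
  meta <- list()
  if (file.exists(meta_path)) {
    kv <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    meta <- as.list(kv$value)
    names(meta) <- kv$key
    if (!is.null(meta$subject_id)) {
      subject_id <- meta$subject_id
      meta$subject_id <- NULL
    }
  }
  connectome(m, labels = colnames(m), subject_id = subject_id, meta = meta)
}

#' Write / read a 6-column motion-parameter trace
#'
#' Whitespace-delimited, one row per volume: three translations (mm) then
#' three rotations (radians), no header — the conventional realignment
#' output format.
#'
#' @param trace volumes x 6 numeric matrix.
#' @param path file path.
#' @return `read_motion` returns the volumes x 6 matrix.
#' @export
write_motion <- function(trace, path) {
  stop_field(ncol(as.matrix(trace)) == 6L, "trace", "must have 6 columns")
  utils::write.table(trace, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) {
    stop(sprintf("motion file has %d columns, expected 6", ncol(m)), call. = FALSE)
  }
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}
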