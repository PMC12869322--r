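# Delimited-text I/O for FC tables, phenotype tables, and ROI time series.
# All files are plain TSV so datasets remain portable and diffable.

#' Write / read a subjects x features FC table
#'
#' TSV with a `subject_id` column followed by one column per FC feature
#' (header `ROIi_ROIj` when built from a connectivity matrix).
#'
#' @param x numeric matrix, subjects x features, with rownames = subject ids.
#' @param path file path.
#' @return `read_fc_table` returns the matrix with subject ids as rownames.
#' @export
write_fc_table <- function(x, path) {
  stopifnot(is.matrix(x))
  df <- data.frame(subject_id = rownames(x) %||% paste0("S", seq_len(nrow(x))),
                   x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_table
#' @export
read_fc_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("FC table contains non-finite values: ", path)
  x
}

#' Write / read a phenotype table
#'
#' Columns: `subject_id`, `diagnosis`, `site`, `age`, `sex`, optionally
#' `symptom_score` (may be missing per subject) and `mean_fd`.
#'
#' @param pheno a data frame with the columns above.
#' @param path file path.
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  ph <- utils::read.delim(path)
  check_phenotype(ph)
  ph
}

#' Validate a phenotype table
#'
#' @param pheno data frame to check.
#' @return the table, invisibly, with `diagnosis`, `site`, `sex` as factors.
#' @export
check_phenotype <- function(pheno) {
  need <- c("subject_id", "diagnosis", "site")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(pheno$subject_id)) stop("duplicated subject_id")
  if (anyNA(pheno$diagnosis) || anyNA(pheno$site)) {
    stop("diagnosis and site must be non-missing")
  }
  for (col in intersect(c("diagnosis", "site", "sex"), names(pheno))) {
    pheno[[col]] <- factor(pheno[[col]])
  }
  invisible(pheno)
}

#' Read an ROI time-series run from delimited text
#'
#' The time-series file is frames x regions with a header row of region
#' labels; the companion FD file holds one FD value (mm) per frame.
#'
#' @param ts_path time-series file.
#' @param tr_seconds sampling interval in seconds.
#' @param fd_path optional FD file; defaults to zero motion.
#' @param ... passed to [roi_run()] (ids).
#' @return an [roi_run()].
#' @export
read_timeseries <- function(ts_path, tr_seconds, fd_path = NULL, ...) {
  sig <- as.matrix(utils::read.delim(ts_path, check.names = FALSE))
  storage.mode(sig) <- "double"
  fd <- if (!is.null(fd_path)) scan(fd_path, quiet = TRUE) else NULL
  roi_run(sig, tr_seconds, fd = fd, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
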