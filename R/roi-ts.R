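#' ROI time-series container
#'
#' One run's observation sequence: a T x D matrix of per-ROI BOLD signal
#' (arbitrary units before normalization, z-units after), with ROI labels,
#' the sampling interval, and run identifiers.
#'
#' @param values numeric T x D matrix, no missing values.
#' @param roi_labels character vector of D ROI names; defaults to the
#'   matrix column names.
#' @param tr sampling interval in seconds per volume.
#' @param subject_id,task_id,run_id identifiers carried through the pipeline.
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(values, roi_labels = colnames(values), tr = 1,
                   subject_id = NA_character_, task_id = NA_character_,
                   run_id = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("ROI time series contains missing or non-finite values")
  }
  if (nrow(values) < 2L) stop("need at least 2 timepoints")
  if (ncol(values) < 2L) stop("need at least 2 ROIs")
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(ncol(values)))
  if (length(roi_labels) != ncol(values)) {
    stop("`roi_labels` length must equal the number of columns")
  }
  colnames(values) <- roi_labels
  structure(
    list(values = values, roi_labels = roi_labels, tr = tr,
         subject_id = subject_id, task_id = task_id, run_id = run_id),
    class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d timepoints x %d ROIs (tr = %gs)\n",
              nrow(x$values), ncol(x$values), x$tr))
  cat("  subject:", x$subject_id, " task:", x$task_id, " run:", x$run_id, "\n")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$values)

#' Motion-regressor container
#'
#' A T x 6 matrix of rigid-body realignment parameters (3 translations in mm,
#' 3 rotations in rad) used as nuisance regressors.
#'
#' @param values numeric T x 6 matrix.
#' @return An object of class `motion_regressors`.
#' @export
motion_regressors <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 6L) stop("motion regressors must have exactly 6 columns")
  if (anyNA(values)) stop("motion regressors contain missing values")
  colnames(values) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(values = values), class = "motion_regressors")
}

#' Read / write ROI time series as tab-separated text
#'
#' Runs are stored as TSV with one row per timepoint and one ROI per column;
#' the header carries the ROI labels.
#'
#' @param x a `roi_ts`.
#' @param path file path.
#' @param ... passed to [roi_ts()] on read (tr, identifiers).
#' @return `write_roi_ts()` returns `path` invisibly; `read_roi_ts()` a
#'   `roi_ts`.
#' @export
write_roi_ts <- function(x, path) {
  stopifnot(inherits(x, "roi_ts"))
  utils::write.table(x$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_roi_ts
#' @export
read_roi_ts <- function(path, ...) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  roi_ts(m, ...)
}

#' @rdname write_roi_ts
#' @export
write_motion <- function(x, path) {
  stopifnot(inherits(x, "motion_regressors"))
  utils::write.table(x$values, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_ts
#' @export
read_motion <- function(path) {
  motion_regressors(as.matrix(utils::read.table(path)))
}

# replace the data matrix, keeping metadata
set_values <- function(ts, values) {
  ts$values <- values
  colnames(ts$values) <- ts$roi_labels
  ts
}
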