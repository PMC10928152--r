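#' Remove head-motion nuisance signal from ROI time series
#'
#' Regresses each ROI column on an intercept plus the 6 realignment
#' parameters and keeps the least-squares residuals, the standard first step
#' of ROI time-series cleaning before state modelling. Degenerate
#' (zero-variance) motion columns are dropped with a warning.
#'
#' @param ts a [roi_ts()].
#' @param motion a [motion_regressors()] with the same number of rows.
#' @return A `roi_ts` of residuals, orthogonal to each retained regressor.
#' @export
regress_nuisance <- function(ts, motion) {
  stopifnot(inherits(ts, "roi_ts"), inherits(motion, "motion_regressors"))
  M <- motion$values
  if (nrow(M) != nrow(ts$values)) {
    stop("motion regressors and time series differ in length")
  }
  keep <- apply(M, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant motion column(s)", sum(!keep)))
    M <- M[, keep, drop = FALSE]
  }
  X <- cbind(1, M)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # collinear motion columns: keep an independent subset
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
    warning("rank-deficient nuisance design; collinear column(s) dropped")
  }
  res <- ts$values - X %*% qr.coef(qx, ts$values)
  set_values(ts, res)
}

#' Linearly detrend ROI time series
#'
#' Removes the per-column best-fit line on the sample index.
#'
#' @param ts a [roi_ts()] with at least 3 timepoints.
#' @return A detrended `roi_ts`.
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- nrow(ts$values)
  if (n < 3L) stop("need at least 3 timepoints to detrend")
  X <- cbind(1, seq_len(n))
  res <- ts$values - X %*% qr.coef(qr(X), ts$values)
  set_values(ts, res)
}

#' Z-score ROI time series
#'
#' Standardizes each column to mean 0 and unit sample standard deviation
#' (divisor T - 1).
#'
#' @param ts a [roi_ts()]; every column must have positive variance.
#' @return A standardized `roi_ts`.
#' @export
zscore <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  sds <- apply(ts$values, 2, stats::sd)
  if (any(sds <= 0)) {
    stop("zero-variance ROI column(s): ",
         paste(ts$roi_labels[sds <= 0], collapse = ", "))
  }
  set_values(ts, scale(ts$values, center = TRUE, scale = sds))
}

#' Full ROI time-series cleaning chain
#'
#' Removes motion nuisance signal and linear drift, then z-scores. The
#' nuisance and trend regressors are projected out in a single joint
#' least-squares step (design: intercept, linear trend, 6 motion columns):
#' this is equivalent to sequential motion regression followed by
#' detrending whenever the regressors are mutually orthogonal, and unlike
#' the strictly sequential composition it leaves the output exactly
#' orthogonal to every regressor and makes the chain idempotent. Motion
#' typically drifts, so the joint projection is the variant that honors
#' both contracts.
#'
#' @param ts a [roi_ts()].
#' @param motion optional [motion_regressors()]; `NULL` cleans drift only.
#' @return A cleaned `roi_ts` with column means 0 and variances 1.
#' @export
preprocess_run <- function(ts, motion = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- nrow(ts$values)
  if (n < 3L) stop("need at least 3 timepoints")
  X <- cbind(1, seq_len(n))
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "motion_regressors"))
    M <- motion$values
    if (nrow(M) != n) stop("motion regressors and time series differ in length")
    keep <- apply(M, 2, stats::sd) > 0
    if (!all(keep)) {
      warning(sprintf("dropping %d constant motion column(s)", sum(!keep)))
      M <- M[, keep, drop = FALSE]
    }
    X <- cbind(X, M)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
    warning("rank-deficient nuisance design; collinear column(s) dropped")
  }
  res <- ts$values - X %*% qr.coef(qx, ts$values)
  zscore(set_values(ts, res))
}
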