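# ---- canonical correlation between occupancy and behavior ------------------

# Core CCA on standardized matrices: symmetric-eigen whitening + SVD.
# Returns weights scaled so canonical variates have unit (regularized)
# variance. Ridge added when a covariance block is near-singular.
cca_core <- function(Xs, Ys, ridge = NULL) {
  Sxx <- stats::cov(Xs); Syy <- stats::cov(Ys); Sxy <- stats::cov(Xs, Ys)
  near_singular <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    min(ev) < 1e-10 * max(ev)
  }
  ridged <- FALSE
  if (is.null(ridge)) {
    ridge <- 0
    if (near_singular(Sxx) || near_singular(Syy)) {
      ridge <- 1e-6 * max(mean(diag(Sxx)), mean(diag(Syy)))
      ridged <- TRUE
    }
  } else if (ridge > 0) ridged <- TRUE
  inv_sqrt <- function(S) {
    e <- eigen(S + ridge * diag(nrow(S)), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                       length(e$values)) %*% t(e$vectors)
  }
  Wx <- inv_sqrt(Sxx); Wy <- inv_sqrt(Syy)
  sv <- svd(Wx %*% Sxy %*% Wy)
  m <- min(ncol(Xs), ncol(Ys))
  list(xweights = Wx %*% sv$u[, seq_len(m), drop = FALSE],
       yweights = Wy %*% sv$v[, seq_len(m), drop = FALSE],
       cors = pmin(sv$d[seq_len(m)], 1), ridged = ridged, ridge = ridge)
}

standardize <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance column in CCA input")
  list(M = sweep(sweep(M, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

select_component <- function(Ys, yweights, orientation) {
  if (is.null(orientation)) return(list(index = 1L, flip = 1))
  scores <- Ys %*% yweights
  al <- suppressWarnings(stats::cor(scores, orientation))
  al[is.na(al)] <- 0
  idx <- which.max(abs(al))
  list(index = idx, flip = if (al[idx] < 0) -1 else 1)
}

#' Canonical correlation between state occupancy and behavior
#'
#' Standardizes both blocks, computes all canonical components, selects the
#' component whose behavioral variate best aligns with the supplied
#' cognitive-control orientation (sign-flipped so the alignment is
#' positive; component 1 when no orientation is given), and assesses the
#' selected canonical correlation by permutation of subject rows (the null
#' statistic is the permuted maximum canonical correlation, a conservative
#' choice). Near-singular blocks are ridge-regularized, flagged.
#'
#' @param X subjects x states occupancy matrix.
#' @param Y subjects x behavioral-measures matrix.
#' @param orientation optional per-subject control-index vector driving
#'   component selection.
#' @param n_perm permutations for the significance test (default 1000).
#' @param seed integer seed.
#' @param ridge optional fixed ridge; `NULL` = automatic.
#' @return An object of class `cca_result`: weights, all canonical
#'   correlations, selected component, permutation `p_value`, `ridged` flag.
#' @export
cca_brain_behavior <- function(X, Y, orientation = NULL, n_perm = 1000L,
                               seed = 1L, ridge = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  if (n <= max(ncol(X), ncol(Y)) + 2L) {
    stop("need more subjects than max(dim X, dim Y) + 2")
  }
  sx <- standardize(X); sy <- standardize(Y)
  fit <- cca_core(sx$M, sy$M, ridge)
  sel <- select_component(sy$M, fit$yweights, orientation)
  fit$xweights[, sel$index] <- fit$xweights[, sel$index] * sel$flip
  fit$yweights[, sel$index] <- fit$yweights[, sel$index] * sel$flip
  obs <- fit$cors[sel$index]
  null_r <- with_seed(derive_seed(seed, 9), {
    vapply(seq_len(n_perm), function(b) {
      cca_core(sx$M, sy$M[sample.int(n), , drop = FALSE], ridge)$cors[1]
    }, numeric(1))
  })
  p <- (1 + sum(null_r >= obs)) / (1 + n_perm)
  structure(
    list(xweights = fit$xweights, yweights = fit$yweights, cors = fit$cors,
         selected = sel$index, selected_r = obs, p_value = p,
         selection_rule = if (is.null(orientation)) "first component" else
           "max |cor| of behavioral variate with control orientation",
         ridged = fit$ridged, n_perm = n_perm,
         x_center = sx$center, x_scale = sx$scale,
         y_center = sy$center, y_scale = sy$scale),
    class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> selected component %d: r = %.3f (perm p = %.4g%s)\n",
              x$selected, x$selected_r, x$p_value,
              if (x$ridged) ", ridged" else ""))
  cat("  all canonical r:", paste(sprintf("%.3f", x$cors), collapse = " "), "\n")
  invisible(x)
}

#' Leave-one-out predictive canonical correlation
#'
#' For each held-out subject, fits the CCA on the remaining subjects
#' (standardizing within the training fold), selects the component by the
#' same orientation rule, projects the held-out subject's occupancy and
#' behavior onto the fold's canonical weights (sign-aligned with the
#' full-sample solution so folds share one orientation), and finally
#' correlates the n held-out brain scores with the n held-out behavior
#' scores (Pearson, two-tailed).
#'
#' @inheritParams cca_brain_behavior
#' @return List with `loo_predicted_r`, `p_value`, and the per-subject
#'   held-out `brain_scores` and `behavior_scores`.
#' @export
predictive_cca_loo <- function(X, Y, orientation = NULL, ridge = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  full_sx <- standardize(X); full_sy <- standardize(Y)
  full <- cca_core(full_sx$M, full_sy$M, ridge)
  full_sel <- select_component(full_sy$M, full$yweights, orientation)
  a_full <- full$xweights[, full_sel$index] * full_sel$flip
  b_full <- full$yweights[, full_sel$index] * full_sel$flip
  xs <- ys <- numeric(n)
  for (i in seq_len(n)) {
    sx <- standardize(X[-i, , drop = FALSE])
    sy <- standardize(Y[-i, , drop = FALSE])
    fit <- cca_core(sx$M, sy$M, ridge)
    sel <- select_component(sy$M, fit$yweights,
                            if (is.null(orientation)) NULL else orientation[-i])
    a <- fit$xweights[, sel$index] * sel$flip
    b <- fit$yweights[, sel$index] * sel$flip
    s <- sign(sum(a * a_full) + sum(b * b_full))
    if (s == 0) s <- 1
    xi <- (X[i, ] - sx$center) / sx$scale
    yi <- (Y[i, ] - sy$center) / sy$scale
    xs[i] <- s * sum(xi * a)
    ys[i] <- s * sum(yi * b)
  }
  ct <- stats::cor.test(xs, ys)
  list(loo_predicted_r = unname(ct$estimate), p_value = ct$p.value,
       brain_scores = xs, behavior_scores = ys)
}

# ---- univariate brain-behavior ---------------------------------------------

#' Univariate correlation of one state's occupancy with behavior
#'
#' Two-tailed Pearson correlation (t-distribution with n - 2 df) between a
#' per-subject occupancy-rate vector and a behavioral index or symptom
#' score.
#'
#' @param occupancy per-subject occupancy rates of one state (n >= 5).
#' @param index per-subject behavioral index or symptom score.
#' @return List with `r`, `p_value`, `n`, and `undefined` flag (zero
#'   variance).
#' @export
univariate_state_behavior <- function(occupancy, index) {
  stopifnot(length(occupancy) == length(index), length(occupancy) >= 5L)
  if (any(!is.finite(occupancy)) || any(!is.finite(index))) {
    stop("non-finite values")
  }
  if (stats::sd(occupancy) == 0 || stats::sd(index) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(index),
                undefined = TRUE))
  }
  ct <- stats::cor.test(occupancy, index)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(index),
       undefined = FALSE)
}

#' Specificity screen across all states
#'
#' Correlates every state's occupancy with the behavioral index and flags
#' whether exactly one state shows a significantly positive association
#' (the expected signature of a single behaviorally relevant shared state).
#' P-values are not adjusted for multiple comparisons by default; a
#' Benjamini-Hochberg option is available.
#'
#' @param occupancy subjects x states occupancy matrix.
#' @param index per-subject behavioral index.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `table` (state, r, p, significant_positive),
#'   `exactly_one` flag, and `flagged_state` (NA when none or several).
#' @export
specificity_screen <- function(occupancy, index, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  occupancy <- as.matrix(occupancy)
  res <- lapply(seq_len(ncol(occupancy)), function(k) {
    univariate_state_behavior(occupancy[, k], index)
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p_value")
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  sig_pos <- !is.na(p) & p < alpha & r > 0
  tab <- data.frame(state = seq_len(ncol(occupancy)), r = r, p_value = p,
                    significant_positive = sig_pos)
  list(table = tab, exactly_one = sum(sig_pos) == 1L,
       flagged_state = if (sum(sig_pos) == 1L) which(sig_pos) else NA_integer_)
}
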