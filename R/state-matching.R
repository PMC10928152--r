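# ---- state space closeness -------------------------------------------------

#' Kullback-Leibler divergence between two brain states
#'
#' Closed-form KL divergence between the states' multivariate Gaussians,
#' both directed values and the symmetrized (Jeffreys) divergence
#' `KL(a||b) + KL(b||a)`, which is the default divergence used for state
#' matching (the directed convention is never decisive: the matched state is
#' the argmax of closeness under either).
#'
#' @param a,b [brain_state()] objects over the same ROIs in the same order.
#' @return List with `kl_ab`, `kl_ba`, and `jeffreys`.
#' @export
gaussian_kld <- function(a, b) {
  stopifnot(inherits(a, "brain_state"), inherits(b, "brain_state"))
  if (!identical(a$roi_labels, b$roi_labels)) {
    stop("brain states are defined over different ROI sets")
  }
  d <- length(a$mean)
  kl_dir <- function(m1, S1, m2, S2) {
    U2 <- chol(S2)
    S2inv <- chol2inv(U2)
    dm <- m2 - m1
    0.5 * (sum(S2inv * S1) + drop(crossprod(dm, S2inv %*% dm)) - d +
             logdet(S2) - logdet(S1))
  }
  kl_ab <- kl_dir(a$mean, a$cov, b$mean, b$cov)
  kl_ba <- kl_dir(b$mean, b$cov, a$mean, a$cov)
  list(kl_ab = kl_ab, kl_ba = kl_ba, jeffreys = kl_ab + kl_ba)
}

#' State space closeness
#'
#' Closeness `c` = 1 / divergence between two states' Gaussians; higher
#' closeness (smaller divergence) means more similar states. Identical
#' states yield infinite closeness, flagged.
#'
#' @inheritParams gaussian_kld
#' @param divergence which divergence to invert: the symmetrized
#'   (`"jeffreys"`, default) or a directed KL.
#' @return List with `c`, `divergence_value`, `direction_convention`, and
#'   `infinite` flag.
#' @export
state_space_closeness <- function(a, b,
                                  divergence = c("jeffreys", "kl_ab", "kl_ba")) {
  divergence <- match.arg(divergence)
  kl <- gaussian_kld(a, b)
  dv <- kl[[divergence]]
  list(c = if (dv > 0) 1 / dv else Inf, divergence_value = dv,
       direction_convention = divergence, kl_ab = kl$kl_ab, kl_ba = kl$kl_ba,
       infinite = dv <= 0)
}

# ---- state temporal closeness ----------------------------------------------

concat_tpp <- function(posteriors) {
  ord <- order(vapply(posteriors, function(p) p$subject_id, character(1)))
  do.call(rbind, lapply(posteriors[ord], function(p) p$tpp))
}

#' State temporal closeness matrix
#'
#' Pearson correlations between every pair of temporal posterior probability
#' columns of two models evaluated on the same runs: rows index the
#' reference model's states (transferred onto the data), columns the target
#' model's own states. Runs are concatenated in subject-id order; a
#' per-subject correlation array is also returned so a few subjects cannot
#' dominate unnoticed. Zero-variance columns (states never visited) yield
#' `NA`, flagged.
#'
#' @param tpp_ref list of `state_posterior` from transferring the reference
#'   model onto the target runs.
#' @param tpp_target list of `state_posterior` from the target model on the
#'   same runs (same order, same lengths).
#' @return List with `r` (K_ref x K_target), `per_subject` (subject x
#'   K_ref x K_target array) and `undefined` flag matrix.
#' @export
temporal_closeness_matrix <- function(tpp_ref, tpp_target) {
  stopifnot(length(tpp_ref) == length(tpp_target))
  for (i in seq_along(tpp_ref)) {
    if (nrow(tpp_ref[[i]]$tpp) != nrow(tpp_target[[i]]$tpp)) {
      stop("TPP pair ", i, " differs in length; must be computed on the same runs")
    }
  }
  A <- concat_tpp(tpp_ref)
  B <- concat_tpp(tpp_target)
  sd_a <- apply(A, 2, stats::sd)
  sd_b <- apply(B, 2, stats::sd)
  r <- suppressWarnings(stats::cor(A, B))
  dimnames(r) <- NULL
  undef <- unname(outer(sd_a == 0, sd_b == 0, "|"))
  r[undef] <- NA_real_
  ids_ref <- vapply(tpp_ref, function(p) p$subject_id, character(1))
  ids_tgt <- vapply(tpp_target, function(p) p$subject_id, character(1))
  ord_r <- order(ids_ref); ord_t <- order(ids_tgt)
  if (!identical(ids_ref[ord_r], ids_tgt[ord_t])) {
    stop("reference and target posteriors cover different subjects")
  }
  per_subj <- array(NA_real_, c(length(tpp_ref), ncol(A), ncol(B)),
                    dimnames = list(ids_ref[ord_r], NULL, NULL))
  for (i in seq_along(ord_r)) {
    per_subj[i, , ] <- suppressWarnings(
      stats::cor(tpp_ref[[ord_r[i]]]$tpp, tpp_target[[ord_t[i]]]$tpp))
  }
  list(r = r, per_subject = per_subj, undefined = undef)
}

# ---- permutation significance ----------------------------------------------

pool_states <- function(models) {
  out <- list()
  for (mn in names(models)) {
    m <- models[[mn]]
    for (k in seq_len(m$K)) {
      out[[length(out) + 1L]] <- list(model = mn, state = k,
                                      bs = m$states[[k]])
    }
  }
  out
}

perm_pvalue <- function(observed, null_samples, n_perm) {
  exceed <- sum(null_samples >= observed)
  floored <- exceed == 0L
  list(p_value = max(exceed, 1L) / n_perm,
       p_label = if (floored) sprintf("< %g", 1 / n_perm) else
         sprintf("%g", exceed / n_perm),
       exceedances = exceed, floored = floored)
}

#' Permutation significance of state space closeness
#'
#' Builds a null distribution by repeatedly drawing two states uniformly at
#' random from the pooled inventory of the supplied models (same- or
#' cross-task draws both allowed, the observed pair itself excluded) and
#' computing their closeness. The p-value is the exceedance fraction, with a
#' `< 1/n_perm` floor when no null draw reaches the observed closeness.
#'
#' @param models named list of `state_model`s whose states form the null
#'   pool (at least 2 states in total).
#' @param observed list `(model, state)` pair naming the observed pair, e.g.
#'   `list(c("ref", 2), c("target", 5))`.
#' @param observed_value the observed closeness `c`.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param divergence passed to [state_space_closeness()].
#' @return List with `p_value`, `p_label`, `exceedances`, `floored`, and
#'   `null_samples` (length `n_perm`).
#' @export
permutation_p_space <- function(models, observed, observed_value,
                                n_perm = 100L, seed = 1L,
                                divergence = "jeffreys") {
  pool <- pool_states(models)
  if (length(pool) < 2L) stop("need at least 2 states in the null pool")
  same_pair <- function(i, j) {
    ids <- lapply(list(pool[[i]], pool[[j]]),
                  function(p) paste(p$model, p$state))
    obs <- lapply(observed, function(o) paste(o[1], o[2]))
    setequal(unlist(ids), unlist(obs))
  }
  null_samples <- with_seed(derive_seed(seed, 6), {
    vapply(seq_len(n_perm), function(b) {
      repeat {
        ij <- sample.int(length(pool), 2L)
        if (!same_pair(ij[1], ij[2])) break
      }
      state_space_closeness(pool[[ij[1]]]$bs, pool[[ij[2]]]$bs,
                            divergence = divergence)$c
    }, numeric(1))
  })
  c(perm_pvalue(observed_value, null_samples, n_perm),
    list(null_samples = null_samples))
}

#' Permutation significance of state temporal closeness
#'
#' Same null-drawing scheme as [permutation_p_space()], with the Pearson
#' correlation between randomly chosen TPP columns (from the pooled
#' reference-transferred and target TPP matrices) as the statistic.
#'
#' @param tpp_ref,tpp_target as in [temporal_closeness_matrix()].
#' @param observed integer pair `c(ref_state, target_state)` of the observed
#'   column pair.
#' @param observed_value the observed correlation.
#' @param n_perm,seed as in [permutation_p_space()].
#' @return As [permutation_p_space()].
#' @export
permutation_p_temporal <- function(tpp_ref, tpp_target, observed,
                                   observed_value, n_perm = 100L, seed = 1L) {
  A <- concat_tpp(tpp_ref)
  B <- concat_tpp(tpp_target)
  M <- cbind(A, B)
  ka <- ncol(A)
  obs_cols <- c(observed[1], ka + observed[2])
  null_samples <- with_seed(derive_seed(seed, 7), {
    vapply(seq_len(n_perm), function(b) {
      repeat {
        ij <- sample.int(ncol(M), 2L)
        if (!setequal(ij, obs_cols)) break
      }
      suppressWarnings(stats::cor(M[, ij[1]], M[, ij[2]]))
    }, numeric(1))
  })
  null_samples[is.na(null_samples)] <- -1
  c(perm_pvalue(observed_value, null_samples, n_perm),
    list(null_samples = null_samples))
}

# ---- full matching ---------------------------------------------------------

#' Match a reference state to a target model's states
#'
#' For every state of the target model, computes state space closeness to
#' the reference state (inverse symmetrized KL of the state Gaussians) and
#' state temporal closeness (correlation between the reference state's
#' transferred posterior time course and the target state's own time course
#' on the target runs). The matched state is the argmax of space closeness;
#' the report records whether the two metrics agree (`consistent`), the
#' permutation p-values of the best value of each metric, and flags ties.
#'
#' @param reference_state integer index of the reference state.
#' @param reference_model,target_model fitted `state_model`s over the same
#'   ROI set.
#' @param target_runs list of [roi_ts()] from the target task (used for the
#'   transfer); if `target_tpp` is supplied it must align with the target
#'   model's stored posteriors.
#' @param n_perm permutations for both significance tests.
#' @param seed integer seed.
#' @param divergence passed to [state_space_closeness()].
#' @param tie_tol relative tolerance under which top-2 closeness values are
#'   flagged as tied (ties broken by temporal closeness).
#' @return An object of class `match_report`.
#' @export
match_states <- function(reference_state, reference_model, target_model,
                         target_runs, n_perm = 100L, seed = 1L,
                         divergence = "jeffreys", tie_tol = 1e-6) {
  stopifnot(inherits(reference_model, "state_model"),
            inherits(target_model, "state_model"))
  if (!identical(reference_model$roi_labels, target_model$roi_labels)) {
    stop("models are defined over different ROI sets")
  }
  ref_bs <- reference_model$states[[reference_state]]
  Kt <- target_model$K
  space <- lapply(seq_len(Kt), function(k) {
    state_space_closeness(ref_bs, target_model$states[[k]], divergence)
  })
  cvals <- vapply(space, `[[`, numeric(1), "c")

  tpp_ref <- apply_state_model(reference_model, target_runs)
  tpp_target <- if (!is.null(target_model$posteriors) &&
                    length(target_model$posteriors) == length(target_runs)) {
    target_model$posteriors
  } else {
    apply_state_model(target_model, target_runs)
  }
  tc <- temporal_closeness_matrix(tpp_ref, tpp_target)
  rvals <- tc$r[reference_state, ]

  best_c <- which.max(cvals)
  best_r <- which.max(rvals)
  sorted <- sort(cvals, decreasing = TRUE)
  tied <- length(cvals) > 1L && is.finite(sorted[1]) &&
    (sorted[1] - sorted[2]) <= tie_tol * max(abs(sorted[1]), 1)
  matched <- best_c
  if (tied && best_r != best_c &&
      abs(cvals[best_r] - cvals[best_c]) <= tie_tol * max(abs(cvals[best_c]), 1)) {
    matched <- best_r
  }

  models <- list(reference = reference_model, target = target_model)
  p_space <- permutation_p_space(
    models, list(c("reference", reference_state), c("target", best_c)),
    cvals[best_c], n_perm = n_perm, seed = seed, divergence = divergence)
  p_temp <- permutation_p_temporal(
    tpp_ref, tpp_target, c(reference_state, best_r), rvals[best_r],
    n_perm = n_perm, seed = seed)

  structure(
    list(reference_state = reference_state,
         candidates = data.frame(
           state = seq_len(Kt), c = cvals,
           divergence = vapply(space, `[[`, numeric(1), "divergence_value"),
           kl_ab = vapply(space, `[[`, numeric(1), "kl_ab"),
           kl_ba = vapply(space, `[[`, numeric(1), "kl_ba"),
           r = rvals),
         matched_state_id = matched,
         best_space = best_c, best_temporal = best_r,
         consistent = best_c == best_r, tied = tied,
         p_space = p_space, p_temporal = p_temp,
         temporal = tc, divergence = divergence, n_perm = n_perm),
    class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> reference state %d -> matched target state %d\n",
              x$reference_state, x$matched_state_id))
  cat(sprintf("  best c = %.3g (p %s), best r = %.3g (p %s), consistent: %s%s\n",
              x$candidates$c[x$best_space], x$p_space$p_label,
              x$candidates$r[x$best_temporal], x$p_temporal$p_label,
              x$consistent, if (x$tied) " [tie]" else ""))
  invisible(x)
}

#' Write a match report as JSON plus a TSV of the c/r table
#'
#' @param report a `match_report`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_match_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "match_report"))
  if (!is.null(tsv_path)) {
    utils::write.table(report$candidates, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    obj <- list(reference_state = report$reference_state,
                matched_state_id = report$matched_state_id,
                consistent = report$consistent, tied = report$tied,
                best_c = report$candidates$c[report$best_space],
                best_r = report$candidates$r[report$best_temporal],
                p_space = report$p_space[c("p_value", "p_label", "exceedances")],
                p_temporal = report$p_temporal[c("p_value", "p_label",
                                                 "exceedances")],
                candidates = report$candidates)
    jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  invisible(report)
}
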