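# ---- leave-one-ROI-out virtual lesions -------------------------------------

#' Remove one ROI from a brain state
#'
#' Marginalizes the state's Gaussian over the removed ROI: the mean entry
#' and the covariance row and column are dropped (for a multivariate
#' Gaussian, dropping coordinates IS the exact marginal).
#'
#' @param state a [brain_state()] with at least 3 ROIs.
#' @param roi ROI label (or integer index) to remove.
#' @return A `brain_state` of dimension D - 1.
#' @export
remove_roi <- function(state, roi) {
  stopifnot(inherits(state, "brain_state"))
  d <- length(state$mean)
  if (d < 3L) stop("need at least 3 ROIs to lesion")
  idx <- if (is.character(roi)) match(roi, state$roi_labels) else as.integer(roi)
  if (is.na(idx) || idx < 1L || idx > d) stop("unknown ROI: ", roi)
  brain_state(state$state_id, state$mean[-idx],
              state$cov[-idx, -idx, drop = FALSE], state$roi_labels[-idx])
}

#' Leave-one-ROI-out lesion profile of a state pair
#'
#' For each ROI, removes it from both states and records
#' `delta = |divergence(full) - divergence(lesioned)|` and the lesion impact
#' `1/delta`. An ROI whose removal barely changes the divergence (small
#' delta, large impact) carries structure that the two states share, so the
#' top-ranked ROI is the one contributing most to the states' similarity.
#' Deltas below `delta_floor` cap the impact at `impact_ceiling`, flagged.
#' Optional permutation significance draws random state pairs from supplied
#' models and computes the same per-ROI delta as the null statistic.
#'
#' @param state_ref,state_target [brain_state()]s over the same ROI set.
#' @param divergence passed to [state_space_closeness()].
#' @param delta_floor,impact_ceiling numerical guards for degenerate deltas.
#' @param models optional named list of `state_model`s for the permutation
#'   null; `NULL` skips significance.
#' @param n_perm,seed permutation settings.
#' @return An object of class `lesion_impact`: a data.frame with columns
#'   `roi`, `delta`, `impact`, `rank`, `capped`, and (if requested) `p_value`.
#' @export
lesion_profile <- function(state_ref, state_target, divergence = "jeffreys",
                           delta_floor = 1e-12, impact_ceiling = 1e12,
                           models = NULL, n_perm = 100L, seed = 1L) {
  stopifnot(inherits(state_ref, "brain_state"),
            inherits(state_target, "brain_state"))
  if (!identical(state_ref$roi_labels, state_target$roi_labels)) {
    stop("states are defined over different ROI sets")
  }
  rois <- state_ref$roi_labels
  deltas <- per_roi_deltas(state_ref, state_target, divergence)
  capped <- deltas < delta_floor
  impact <- ifelse(capped, impact_ceiling, 1 / deltas)
  out <- data.frame(roi = rois, delta = deltas, impact = impact,
                    rank = rank(-impact, ties.method = "min"),
                    capped = capped, row.names = NULL)
  if (!is.null(models)) {
    pool <- pool_states(models)
    null_top <- with_seed(derive_seed(seed, 8), {
      replicate(n_perm, {
        ij <- sample.int(length(pool), 2L)
        max(per_roi_deltas(pool[[ij[1]]]$bs, pool[[ij[2]]]$bs, divergence))
      })
    })
    out$p_value <- vapply(deltas, function(d) {
      perm_pvalue(1 / max(d, delta_floor), 1 / pmax(null_top, delta_floor),
                  n_perm)$p_value
    }, numeric(1))
  }
  structure(out, class = c("lesion_impact", "data.frame"),
            divergence = divergence)
}

per_roi_deltas <- function(a, b, divergence) {
  full <- state_space_closeness(a, b, divergence)$divergence_value
  vapply(a$roi_labels, function(roi) {
    les <- state_space_closeness(remove_roi(a, roi), remove_roi(b, roi),
                                 divergence)$divergence_value
    abs(full - les)
  }, numeric(1))
}

#' Write a lesion impact table as TSV
#'
#' @param impact a [lesion_profile()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lesion_impact <- function(impact, path) {
  stopifnot(inherits(impact, "lesion_impact"))
  utils::write.table(impact, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
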