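# ---- occupancy and transition summaries ------------------------------------

#' Occupancy rates of a run's states
#'
#' Fraction of run time each state occupies. The primary (hard) variant
#' counts timepoints where the state attains the maximum posterior (ties go
#' to the lowest state index, counted and flagged); the mean-posterior
#' variant averages the temporal posterior probabilities. Both sum to 1.
#'
#' @param posterior a [state_posterior()].
#' @return List with `hard` and `soft` K-vectors, plus `n_ties`.
#' @export
occupancy_rates <- function(posterior) {
  stopifnot(inherits(posterior, "state_posterior"))
  tpp <- posterior$tpp
  lab <- max.col(tpp, ties.method = "first")
  rowmax <- tpp[cbind(seq_len(nrow(tpp)), lab)]
  n_ties <- sum(rowSums(abs(tpp - rowmax) < 1e-12) > 1L)
  K <- ncol(tpp)
  hard <- tabulate(lab, nbins = K) / nrow(tpp)
  list(hard = hard, soft = colMeans(tpp), n_ties = n_ties)
}

#' Per-subject occupancy table
#'
#' @param posteriors list of [state_posterior()] (one per subject/run).
#' @param type `"hard"` (argmax assignment, default) or `"soft"`
#'   (mean posterior).
#' @return A subjects x states matrix with subject ids as row names.
#' @export
occupancy_table <- function(posteriors, type = c("hard", "soft")) {
  type <- match.arg(type)
  out <- t(vapply(posteriors, function(p) occupancy_rates(p)[[type]],
                  numeric(ncol(posteriors[[1]]$tpp))))
  rownames(out) <- unname(vapply(posteriors, function(p) p$subject_id,
                                 character(1)))
  colnames(out) <- paste0("state", seq_len(ncol(out)))
  out
}

#' Hard state sequence of a run
#'
#' @param posterior a [state_posterior()].
#' @return Integer vector of argmax state labels (ties to lowest index).
#' @export
state_sequence <- function(posterior) {
  stopifnot(inherits(posterior, "state_posterior"))
  max.col(posterior$tpp, ties.method = "first")
}

#' Empirical transition matrix from a label sequence
#'
#' Row-normalized transition counts; rows with zero counts are set uniform
#' and flagged via the `"empty_rows"` attribute.
#'
#' @param labels integer state sequence.
#' @param K number of states (defaults to `max(labels)`).
#' @return K x K row-stochastic matrix.
#' @export
empirical_transition_matrix <- function(labels, K = max(labels)) {
  n <- length(labels)
  counts <- matrix(0, K, K)
  if (n > 1L) {
    tr <- table(factor(labels[-n], levels = 1:K),
                factor(labels[-1], levels = 1:K))
    counts <- unclass(tr)
  }
  rs <- rowSums(counts)
  empty <- rs == 0
  out <- counts
  out[!empty, ] <- counts[!empty, , drop = FALSE] / rs[!empty]
  out[empty, ] <- 1 / K
  attr(out, "empty_rows") <- unname(which(empty))
  dimnames(out) <- NULL
  out
}

#' Export per-state activation and connectivity profiles
#'
#' Writes, for each state, the mean activation profile and the ROI x ROI
#' covariance ("functional connectivity") as ROI-labelled TSV tables.
#'
#' @param model a `state_model`.
#' @param dir output directory (created if missing); `NULL` returns the
#'   tables without writing.
#' @return Named list with `means` (states x ROI data.frame) and `covs`
#'   (list of ROI-labelled matrices), invisibly when written.
#' @export
export_state_profiles <- function(model, dir = NULL) {
  stopifnot(inherits(model, "state_model"))
  means <- do.call(rbind, lapply(model$states, function(s) s$mean))
  rownames(means) <- paste0("state", seq_len(model$K))
  means_df <- data.frame(state = rownames(means), means, check.names = FALSE,
                         row.names = NULL)
  covs <- lapply(model$states, function(s) s$cov)
  names(covs) <- rownames(means)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(means_df, file.path(dir, "state_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (k in seq_len(model$K)) {
      utils::write.table(
        data.frame(roi = model$roi_labels, covs[[k]], check.names = FALSE),
        file.path(dir, sprintf("state%d_cov.tsv", k)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(list(means = means_df, covs = covs)))
  }
  list(means = means_df, covs = covs)
}
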