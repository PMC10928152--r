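#' Pipeline configuration
#'
#' Bundles the simulation settings with the model-fitting, matching and
#' statistics settings used by [run_pipeline()].
#'
#' @param sim a [sim_config()]; defines the synthetic cohort (or is ignored
#'   when a prebuilt cohort is passed to [run_pipeline()]).
#' @param K_init initial state count for every task's fit (default 15).
#' @param n_restarts,max_iter,tol fitting controls, see [fit_state_model()].
#' @param n_perm_match permutations for matching significance.
#' @param n_perm_cca permutations for the CCA significance test.
#' @param preprocess logical; clean each run (motion regression, detrend,
#'   z-score) before fitting.
#' @param seed master integer seed; all stage seeds derive from it.
#' @param out_dir optional output directory for tables and reports.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), K_init = 15L, n_restarts = 5L,
                       max_iter = 500L, tol = 1e-6, n_perm_match = 100L,
                       n_perm_cca = 1000L, preprocess = TRUE, seed = 1L,
                       out_dir = NULL) {
  stopifnot(sim$reference_task %in% sim$tasks)
  structure(list(sim = sim, K_init = as.integer(K_init),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 n_perm_match = as.integer(n_perm_match),
                 n_perm_cca = as.integer(n_perm_cca),
                 preprocess = preprocess, seed = as.integer(seed),
                 out_dir = out_dir),
            class = c("run_config", "list"))
}

stage_msg <- function(verbose, ...) if (verbose) message("[mdstates] ", ...)

#' Run the full brain-state analysis pipeline
#'
#' Orchestrates, from a single configuration: cohort simulation (unless a
#' prebuilt cohort is supplied), per-run preprocessing, one group model fit
#' per task, transfer of the reference model onto every other task, state
#' matching (space + temporal closeness with permutation significance),
#' leave-one-ROI-out lesion analysis of each matched pair, occupancy
#' tables, behavioral indices, and brain-behavior statistics (CCA,
#' predictive LOO CCA, univariate specificity screen). All stages are pure
#' functions of (inputs, config, seed); rerunning with the same seeds
#' reproduces every number.
#'
#' @param config a [run_config()].
#' @param cohort optional prebuilt [generate_multitask_cohort()] cohort.
#' @param reference_state integer index of the reference state to match; by
#'   default the fitted reference-task state closest (symmetrized KL) to
#'   the generator's planted shared state, falling back to the
#'   highest-usage state for null cohorts or real data.
#' @param verbose print stage progress.
#' @return A `pipeline_result` bundle: fitted `models`, per-task
#'   `match` reports, `lesion` tables, `occupancy` tables, `behavior`
#'   statistics, and a reproducibility `manifest`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         reference_state = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  if (is.null(cohort)) {
    stage_msg(verbose, "simulating cohort")
    cohort <- generate_multitask_cohort(sim)
  }
  tasks <- cohort$tasks
  ref_task <- sim$reference_task
  if (!ref_task %in% tasks) stop("reference task not present in the cohort")

  runs <- cohort$runs
  if (config$preprocess) {
    stage_msg(verbose, "preprocessing runs")
    for (tk in tasks) {
      mo <- cohort$motion[[tk]]
      runs[[tk]] <- lapply(stats::setNames(names(runs[[tk]]), names(runs[[tk]])),
                           function(sid) {
                             preprocess_run(runs[[tk]][[sid]],
                                            if (is.null(mo)) NULL else mo[[sid]])
                           })
    }
  }

  stage_msg(verbose, "fitting state models")
  models <- list()
  for (tk in tasks) {
    models[[tk]] <- fit_state_model(
      runs[[tk]], K_init = config$K_init, n_restarts = config$n_restarts,
      max_iter = config$max_iter, tol = config$tol,
      seed = derive_seed(config$seed, 10, match(tk, tasks)))
  }
  ref_model <- models[[ref_task]]

  if (is.null(reference_state)) {
    reference_state <- pick_reference_state(ref_model, cohort, ref_task)
  }

  stage_msg(verbose, "matching states and lesioning")
  targets <- setdiff(tasks, ref_task)
  match <- lesion <- list()
  for (tk in targets) {
    match[[tk]] <- match_states(
      reference_state, ref_model, models[[tk]], runs[[tk]],
      n_perm = config$n_perm_match,
      seed = derive_seed(config$seed, 11, match(tk, tasks)))
    lesion[[tk]] <- lesion_profile(
      ref_model$states[[reference_state]],
      models[[tk]]$states[[match[[tk]]$matched_state_id]])
  }

  stage_msg(verbose, "occupancy and behavior statistics")
  occupancy <- lapply(models, function(m) occupancy_table(m$posteriors))
  behavior <- NULL
  if (!is.null(cohort$behavior)) {
    behavior <- list()
    for (tk in targets) {
      beh <- cohort$behavior[cohort$behavior$task == tk, ]
      beh <- beh[match(rownames(occupancy[[tk]]), beh$subject), ]
      occ <- occupancy[[tk]]
      matched <- match[[tk]]$matched_state_id
      Y <- cbind(index = beh$index)
      cca <- tryCatch(
        cca_brain_behavior(occ, Y, orientation = beh$index,
                           n_perm = config$n_perm_cca,
                           seed = derive_seed(config$seed, 12,
                                              match(tk, tasks))),
        error = function(e) NULL)
      loo <- tryCatch(predictive_cca_loo(occ, Y, orientation = beh$index),
                      error = function(e) NULL)
      behavior[[tk]] <- list(
        matched_state = matched,
        univariate = univariate_state_behavior(occ[, matched], beh$index),
        screen = specificity_screen(occ, beh$index),
        cca = cca, loo = loo)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mdstates")),
    seed = config$seed, K_init = config$K_init,
    tasks = tasks, reference_task = ref_task,
    reference_state = reference_state,
    k_effective = vapply(models, function(m) m$K, integer(1)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  out <- structure(
    list(cohort = cohort, models = models, reference_state = reference_state,
         match = match, lesion = lesion, occupancy = occupancy,
         behavior = behavior, manifest = manifest, config = config),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_result(out, config$out_dir)
  out
}

# Reference state: the fitted state nearest the planted shared state when
# ground truth is available, otherwise the highest-usage state.
pick_reference_state <- function(ref_model, cohort, ref_task) {
  truth <- cohort$truth
  if (!is.null(truth$shared_state_id)) {
    s <- truth$shared_state_id[[ref_task]]
    true_bs <- brain_state(s, truth$state_means[[ref_task]][s, ],
                           truth$state_covs[[ref_task]][[s]],
                           truth$roi_labels)
    dv <- vapply(ref_model$states, function(st) {
      gaussian_kld(true_bs, st)$jeffreys
    }, numeric(1))
    which.min(dv)
  } else {
    which.max(ref_model$ard_weights)
  }
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  K effective:", paste(names(x$manifest$k_effective), "=",
                              x$manifest$k_effective, collapse = ", "), "\n")
  for (tk in names(x$match)) {
    m <- x$match[[tk]]
    cat(sprintf("  %s: matched state %d (c = %.3g, r = %.3g, consistent: %s)\n",
                tk, m$matched_state_id, m$candidates$c[m$best_space],
                m$candidates$r[m$best_temporal], m$consistent))
  }
  invisible(x)
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tk in names(result$match)) {
    write_match_report(result$match[[tk]],
                       json_path = file.path(dir, paste0("match_", tk, ".json")),
                       tsv_path = file.path(dir, paste0("match_", tk, ".tsv")))
    write_lesion_impact(result$lesion[[tk]],
                        file.path(dir, paste0("lesion_", tk, ".tsv")))
  }
  for (tk in names(result$occupancy)) {
    utils::write.table(
      data.frame(subject = rownames(result$occupancy[[tk]]),
                 result$occupancy[[tk]], check.names = FALSE),
      file.path(dir, paste0("occupancy_", tk, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (tk in names(result$models)) {
    write_state_model(result$models[[tk]],
                      file.path(dir, paste0("model_", tk, ".json")))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
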