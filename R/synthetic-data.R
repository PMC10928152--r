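#' Default multiple-demand ROI labels
#'
#' The 11-region frontoparietal/cingulo-opercular set used throughout:
#' bilateral anterior insula, middle frontal gyrus, frontal eye field and
#' intraparietal sulcus, plus dorsomedial prefrontal, ventromedial prefrontal
#' and posterior cingulate cortices.
#'
#' @return Character vector of length 11.
#' @export
md_roi_labels <- function() {
  c("lAI", "rAI", "lMFG", "rMFG", "lFEF", "rFEF", "lIPS", "rIPS",
    "DMPFC", "VMPFC", "PCC")
}

#' Markov-switching Gaussian ground truth for a multi-task cohort
#'
#' Samples the generative parameters the simulator draws from: per-task state
#' inventories (Gaussian mean "activation" and covariance "connectivity"),
#' sticky row-stochastic transition matrices, and a single shared state
#' planted at a (seed-determined) position in every task's inventory.
#' Per-subject scalar biases tilt transition mass toward the shared state so
#' its dwell time varies across subjects.
#'
#' @param tasks character vector of task names (>= 1).
#' @param n_states number of latent states per task.
#' @param roi_labels ROI names; their length sets the dimension D.
#' @param n_subjects number of subjects (sets the bias vector length).
#' @param shared logical; plant one state with identical (mean, covariance)
#'   across tasks. `FALSE` gives a null cohort.
#' @param separation sd (z-units) of state mean coordinates; with unit-scale
#'   emission covariances, 1.0 gives well-separated states in D >= 10.
#' @param self_prob diagonal (dwell) probability of each transition row.
#' @param perturb_sd sd of per-task jitter applied to the shared state's mean
#'   (0 = exact replica), used to probe matching robustness.
#' @param occupancy_bias_sd sd of the per-subject log-tilt on transition mass
#'   into the shared state.
#' @param noise_sd sd of additional isotropic measurement noise.
#' @param seed integer seed; the truth is a pure function of the arguments.
#' @return An object of class `ground_truth`.
#' @export
simulate_ground_truth <- function(tasks = c("nback", "axcpt"),
                                  n_states = 4L,
                                  roi_labels = md_roi_labels(),
                                  n_subjects = 40L,
                                  shared = TRUE,
                                  separation = 1.0,
                                  self_prob = 0.85,
                                  perturb_sd = 0,
                                  occupancy_bias_sd = 0.5,
                                  noise_sd = 0,
                                  seed = 1L) {
  stopifnot(length(tasks) >= 1L, n_states >= 1L, self_prob > 0, self_prob < 1)
  d <- length(roi_labels)
  with_seed(derive_seed(seed, 1), {
    shared_mean <- stats::rnorm(d, 0, separation)
    shared_cov <- rand_pd_cov(d)
    transition <- initial <- means <- covs <- list()
    shared_id <- stats::setNames(integer(length(tasks)), tasks)
    for (ti in seq_along(tasks)) {
      K <- n_states
      mu <- matrix(stats::rnorm(K * d, 0, separation), K, d)
      sg <- lapply(seq_len(K), function(i) rand_pd_cov(d))
      if (shared) {
        s <- sample.int(K, 1)
        shared_id[ti] <- s
        mu[s, ] <- shared_mean + stats::rnorm(d, 0, perturb_sd)
        sg[[s]] <- shared_cov
      }
      A <- matrix(0, K, K)
      for (j in seq_len(K)) {
        if (K == 1L) {
          A[j, ] <- 1
        } else {
          off <- stats::rgamma(K - 1, 1, 1)
          A[j, -j] <- (1 - self_prob) * off / sum(off)
          A[j, j] <- self_prob
        }
      }
      p0 <- stats::rgamma(K, 2, 1)
      transition[[tasks[ti]]] <- A
      initial[[tasks[ti]]] <- p0 / sum(p0)
      colnames(mu) <- roi_labels
      means[[tasks[ti]]] <- mu
      covs[[tasks[ti]]] <- sg
    }
    bias <- stats::rnorm(n_subjects, 0, occupancy_bias_sd)
    structure(
      list(tasks = tasks, n_states = as.integer(n_states),
           roi_labels = roi_labels,
           shared_state_id = if (shared) shared_id else NULL,
           transition = transition, initial = initial,
           state_means = means, state_covs = covs,
           subject_occupancy_bias = bias, perturb_sd = perturb_sd,
           noise_sd = noise_sd, seed = as.integer(seed)),
      class = "ground_truth")
  })
}

#' Validate a ground-truth object
#'
#' Checks row-stochasticity of every transition matrix, symmetry and positive
#' definiteness of every state covariance, and (when planted) that the shared
#' state is replicated across tasks up to the stated mean perturbation.
#'
#' @param truth a `ground_truth`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  for (tk in truth$tasks) {
    A <- truth$transition[[tk]]
    if (any(A < 0) || max(abs(rowSums(A) - 1)) > 1e-12) {
      stop("transition matrix for task ", tk, " is not row-stochastic")
    }
    for (S in truth$state_covs[[tk]]) {
      if (max(abs(S - t(S))) > 1e-10) stop("asymmetric state covariance")
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
        stop("state covariance is not positive definite")
      }
    }
  }
  if (!is.null(truth$shared_state_id) && length(truth$tasks) > 1L) {
    ref <- truth$tasks[1]
    m1 <- truth$state_means[[ref]][truth$shared_state_id[[ref]], ]
    tol <- max(1e-10, 6 * truth$perturb_sd * sqrt(length(m1)))
    for (tk in truth$tasks[-1]) {
      m2 <- truth$state_means[[tk]][truth$shared_state_id[[tk]], ]
      if (sqrt(sum((m1 - m2)^2)) > tol) {
        stop("shared state means differ beyond the stated perturbation")
      }
    }
  }
  invisible(TRUE)
}

# Tilt transition mass toward state `s` by exp(bias), rows renormalized.
tilt_transition <- function(A, s, bias) {
  if (bias == 0) return(A)
  A[, s] <- A[, s] * exp(bias)
  A / rowSums(A)
}

#' Generate one task's ROI time series for a set of subjects
#'
#' Each run is a first-order Markov chain of hidden states with multivariate
#' Gaussian emissions, plus optional linear drift and motion-correlated
#' nuisance signal. Per-subject occupancy of the shared state follows the
#' bias-tilted stationary distribution of the transition matrix. Hidden state
#' labels are returned for testing against ground truth.
#'
#' @param truth a [simulate_ground_truth()] result.
#' @param task task name present in `truth$tasks`.
#' @param n_subjects number of subjects (must not exceed the bias vector).
#' @param n_timepoints run length T (>= 50).
#' @param tr sampling interval in seconds.
#' @param drift_range max absolute per-ROI linear drift over the run
#'   (z-units end-to-start); 0 disables.
#' @param motion_weight scale of the motion-to-ROI linear mixing; 0 disables.
#' @return List with `runs` (named list of [roi_ts()]), `labels` (hidden
#'   state sequences), and `motion` (per-subject [motion_regressors()], or
#'   `NULL` when `motion_weight = 0`).
#' @export
generate_task_dataset <- function(truth, task, n_subjects,
                                  n_timepoints = 300L, tr = 0.72,
                                  drift_range = 0, motion_weight = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!task %in% truth$tasks) stop("unknown task: ", task)
  if (n_timepoints < 50L) stop("n_timepoints must be >= 50")
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  A0 <- truth$transition[[task]]
  if (max(abs(rowSums(A0) - 1)) > 1e-10) stop("non-stochastic transition matrix")
  ti <- match(task, truth$tasks)
  d <- length(truth$roi_labels)
  K <- nrow(A0)
  shared <- if (is.null(truth$shared_state_id)) NA_integer_ else
    truth$shared_state_id[[task]]
  runs <- labels <- motion <- list()
  for (s in seq_len(n_subjects)) {
    bias <- if (s <= length(truth$subject_occupancy_bias))
      truth$subject_occupancy_bias[s] else 0
    A <- if (!is.na(shared)) tilt_transition(A0, shared, bias) else A0
    p0 <- truth$initial[[task]]
    if (!is.na(shared)) {
      p0 <- p0 * ifelse(seq_len(K) == shared, exp(bias), 1)
      p0 <- p0 / sum(p0)
    }
    sid <- sprintf("sub%03d", s)
    with_seed(derive_seed(truth$seed, 2, ti, s), {
      z <- integer(n_timepoints)
      z[1] <- sample.int(K, 1, prob = p0)
      for (t in 2:n_timepoints) z[t] <- sample.int(K, 1, prob = A[z[t - 1], ])
      X <- matrix(0, n_timepoints, d)
      for (k in unique(z)) {
        idx <- which(z == k)
        X[idx, ] <- rmvnorm_chol(length(idx), truth$state_means[[task]][k, ],
                                 truth$state_covs[[task]][[k]])
      }
      if (truth$noise_sd > 0) {
        X <- X + matrix(stats::rnorm(length(X), 0, truth$noise_sd),
                        nrow(X), ncol(X))
      }
      if (drift_range > 0) {
        slope <- stats::runif(d, -drift_range, drift_range)
        X <- X + (seq_len(n_timepoints) / n_timepoints) %o% slope
      }
      mo <- NULL
      if (motion_weight > 0) {
        M <- apply(matrix(stats::rnorm(n_timepoints * 6, 0, 0.02),
                          n_timepoints, 6), 2, cumsum)
        W <- matrix(stats::rnorm(6 * d), 6, d) / sqrt(6)
        X <- X + motion_weight * (M %*% W)
        mo <- motion_regressors(M)
      }
      runs[[sid]] <- roi_ts(X, truth$roi_labels, tr = tr, subject_id = sid,
                            task_id = task, run_id = "run1")
      labels[[sid]] <- z
      motion[[sid]] <- mo
    })
  }
  list(runs = runs, labels = labels,
       motion = if (motion_weight > 0) motion else NULL)
}

#' Default simulation configuration
#'
#' Study-scale defaults for the synthetic cohort: two tasks, 40 subjects per
#' task, T = 300 volumes at TR 0.72 s, 4 states per task over the 11
#' multiple-demand ROIs, a planted shared state, and a subject-level
#' behavioral index coupled to shared-state occupancy at population
#' correlation 0.5.
#'
#' @param ... named overrides of any field.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    tasks = c("nback", "axcpt"),
    reference_task = "nback",
    n_subjects = 40L,
    n_timepoints = 300L,
    n_states = 4L,
    roi_labels = md_roi_labels(),
    tr = 0.72,
    shared = TRUE,
    separation = 1.0,
    self_prob = 0.85,
    perturb_sd = 0,
    occupancy_bias_sd = 0.5,
    noise_sd = 0,
    drift_range = 0,
    motion_weight = 0,
    behavior_r = 0.5,
    behavior_intercept = 0,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("sim_config", "list"))
}

#' Generate a multi-task synthetic cohort
#'
#' Draws a ground truth, simulates every (subject, task) run, and builds a
#' behavioral table whose index is coupled to each subject's realized
#' shared-state occupancy at the configured population correlation
#' (`behavior_r`); set `shared = FALSE` for a null cohort (requesting a
#' behavioral coupling there is an error).
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_cohort` with `runs`, `labels`, `motion`,
#'   `behavior`, `truth`, and `config` fields.
#' @export
generate_multitask_cohort <- function(config = sim_config()) {
  stopifnot(length(config$tasks) >= 2L,
            config$reference_task %in% config$tasks)
  if (!config$shared && !is.null(config$behavior_r) && config$behavior_r != 0) {
    stop("behavioral coupling requested without a shared state")
  }
  truth <- simulate_ground_truth(
    tasks = config$tasks, n_states = config$n_states,
    roi_labels = config$roi_labels, n_subjects = config$n_subjects,
    shared = config$shared, separation = config$separation,
    self_prob = config$self_prob, perturb_sd = config$perturb_sd,
    occupancy_bias_sd = config$occupancy_bias_sd, noise_sd = config$noise_sd,
    seed = config$seed)
  runs <- labels <- motion <- list()
  for (tk in config$tasks) {
    ds <- generate_task_dataset(truth, tk, config$n_subjects,
                                config$n_timepoints, tr = config$tr,
                                drift_range = config$drift_range,
                                motion_weight = config$motion_weight)
    runs[[tk]] <- ds$runs
    labels[[tk]] <- ds$labels
    motion[[tk]] <- ds$motion
  }
  behavior <- NULL
  if (config$shared) {
    rows <- list()
    for (tk in config$tasks) {
      s_id <- truth$shared_state_id[[tk]]
      occ <- vapply(labels[[tk]], function(z) mean(z == s_id), numeric(1))
      r <- config$behavior_r
      with_seed(derive_seed(config$seed, 3, match(tk, config$tasks)), {
        eps <- stats::rnorm(length(occ))
        zocc <- as.vector(scale(occ))
        index <- config$behavior_intercept + r * zocc + sqrt(1 - r^2) * eps
      })
      rows[[tk]] <- data.frame(subject = names(occ), task = tk,
                               shared_occupancy = unname(occ),
                               index = index, row.names = NULL)
    }
    behavior <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  structure(list(tasks = config$tasks, runs = runs, labels = labels,
                 motion = motion, behavior = behavior, truth = truth,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d task(s) x %d subject(s), T = %d, D = %d\n",
              length(x$tasks), x$config$n_subjects, x$config$n_timepoints,
              length(x$truth$roi_labels)))
  cat("  tasks:", paste(x$tasks, collapse = ", "),
      if (!is.null(x$truth$shared_state_id)) "(shared state planted)" else
        "(null cohort)", "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Runs as TSV (T rows, header = ROI labels), motion as 6-column whitespace
#' text, the behavioral table as TSV, ground truth as JSON, and the
#' configuration as YAML.
#'
#' @param cohort a [generate_multitask_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tk in cohort$tasks) {
    td <- file.path(dir, tk)
    dir.create(td, showWarnings = FALSE)
    for (sid in names(cohort$runs[[tk]])) {
      write_roi_ts(cohort$runs[[tk]][[sid]],
                   file.path(td, paste0(sid, "_ts.tsv")))
      if (!is.null(cohort$motion[[tk]])) {
        write_motion(cohort$motion[[tk]][[sid]],
                     file.path(td, paste0(sid, "_motion.txt")))
      }
    }
  }
  if (!is.null(cohort$behavior)) {
    utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- cohort$truth
  truth_json <- list(
    tasks = truth$tasks, n_states = truth$n_states,
    roi_labels = truth$roi_labels,
    shared_state_id = as.list(truth$shared_state_id),
    transition = lapply(truth$transition, unclass),
    initial = truth$initial,
    state_means = lapply(truth$state_means, unclass),
    state_covs = truth$state_covs,
    subject_occupancy_bias = truth$subject_occupancy_bias,
    perturb_sd = truth$perturb_sd, noise_sd = truth$noise_sd,
    seed = truth$seed)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate stop-signal task trials from the horse-race model
#'
#' Go reaction times are truncated-normal; on stop trials an independent race
#' is run between the go process and the stop process (stop-signal delay +
#' true SSRT). The stop-signal delay follows a 1-up/1-down staircase so that
#' responding on stop trials converges to about 50%. A tie (go RT exactly
#' equal to SSD + SSRT) counts as a successful stop.
#'
#' @param go_mu,go_sd mean and sd of the go RT distribution (ms), truncated
#'   below at 1 ms.
#' @param ssrt_true true stop-signal reaction time (ms).
#' @param n_go,n_stop trial counts (`n_stop >= 20`).
#' @param staircase_step staircase step size (ms).
#' @param ssd_start initial stop-signal delay (ms).
#' @param seed integer seed.
#' @return A `data.frame` with columns `trial_type` ("go"/"stop"), `rt`
#'   (NA when no response), `responded`, and `ssd` (NA on go trials).
#' @export
generate_race_model_trials <- function(go_mu = 500, go_sd = 100,
                                       ssrt_true = 250, n_go = 600,
                                       n_stop = 200, staircase_step = 50,
                                       ssd_start = 200, seed = 1L) {
  stopifnot(go_mu > 0, go_sd >= 0, ssrt_true >= 0, staircase_step > 0,
            n_stop >= 20L)
  with_seed(derive_seed(seed, 4), {
    rtrunc_go <- function(n) {
      out <- stats::rnorm(n, go_mu, go_sd)
      while (any(out < 1)) {
        bad <- out < 1
        out[bad] <- stats::rnorm(sum(bad), go_mu, go_sd)
      }
      out
    }
    n <- n_go + n_stop
    is_stop <- sample(rep(c(FALSE, TRUE), c(n_go, n_stop)))
    go_rt <- rtrunc_go(n)
    rt <- numeric(n); responded <- logical(n); ssd <- rep(NA_real_, n)
    cur_ssd <- ssd_start
    for (i in seq_len(n)) {
      if (!is_stop[i]) {
        rt[i] <- go_rt[i]; responded[i] <- TRUE
      } else {
        ssd[i] <- cur_ssd
        responded[i] <- go_rt[i] < cur_ssd + ssrt_true
        rt[i] <- if (responded[i]) go_rt[i] else NA_real_
        # 1-up/1-down: a response (failed stop) makes stopping easier
        cur_ssd <- if (responded[i]) max(0, cur_ssd - staircase_step) else
          cur_ssd + staircase_step
      }
    }
    data.frame(trial_type = ifelse(is_stop, "stop", "go"), rt = rt,
               responded = responded, ssd = ssd)
  })
}
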