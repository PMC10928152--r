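#' @useDynLib mdstates, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- conjugate-prior bookkeeping -------------------------------------------

# log multivariate gamma and its digamma
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}
mvdigamma <- function(a, p) sum(digamma(a + (1 - seq_len(p)) / 2))

# log normalizer of a Wishart(W, nu) density (Bishop's B(W, nu), logged)
wishart_lnB <- function(W, nu) {
  d <- nrow(W)
  -(nu / 2) * logdet(W) - (nu * d / 2) * log(2) - lmvgamma(nu / 2, d)
}

kl_dirichlet <- function(a, b) {
  if (length(b) == 1L) b <- rep(b, length(a))
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(b)) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sum(a))))
}

# KL( NW(mq, bq, Wq, nuq) || NW(mp, bp, Wp, nup) ), Wishart scale convention
kl_normal_wishart <- function(mq, bq, Wq, nuq, mp, bp, Wp, nup) {
  d <- length(mq)
  Elogdet <- mvdigamma(nuq / 2, d) + d * log(2) + logdet(Wq)
  Wp_inv <- chol2inv(chol(Wp))
  kl_w <- wishart_lnB(Wq, nuq) - wishart_lnB(Wp, nup) +
    ((nuq - nup) / 2) * Elogdet +
    (nuq / 2) * sum(Wp_inv * Wq) - nuq * d / 2
  dm <- mq - mp
  kl_n <- 0.5 * (bp * nuq * drop(crossprod(dm, Wq %*% dm)) +
                   d * bp / bq - d + d * log(bq / bp))
  kl_w + kl_n
}

default_priors <- function(d) {
  nu0 <- d + 2
  list(alpha0 = 1e-2,            # Dirichlet concentration, initial probs
       eps0 = 1e-2,              # Dirichlet concentration, transition rows
       beta0 = 1e-3,             # prior precision on state means
       m0 = rep(0, d),
       nu0 = nu0,
       W0 = diag(d) / nu0)       # prior expected precision = identity
}

# ---- VB E/M machinery ------------------------------------------------------

vb_mstep <- function(X, gamma, xi_sum, gamma_init, pr) {
  d <- ncol(X); K <- ncol(gamma)
  Nk <- colSums(gamma) + 1e-12
  xbar <- crossprod(gamma, X) / Nk                     # K x d
  alpha <- pr$alpha0 + as.numeric(gamma_init)
  eps <- pr$eps0 + xi_sum
  beta <- pr$beta0 + Nk
  nu <- pr$nu0 + Nk
  m <- matrix(0, K, d)
  W <- vector("list", K)
  W0_inv <- chol2inv(chol(pr$W0))
  for (k in seq_len(K)) {
    m[k, ] <- (pr$beta0 * pr$m0 + Nk[k] * xbar[k, ]) / beta[k]
    Xc <- sweep(X, 2, xbar[k, ])
    Sk <- crossprod(Xc * gamma[, k], Xc)               # Nk * S_k
    dm <- xbar[k, ] - pr$m0
    Winv <- W0_inv + Sk + (pr$beta0 * Nk[k] / beta[k]) * tcrossprod(dm)
    W[[k]] <- chol2inv(chol((Winv + t(Winv)) / 2))
  }
  list(alpha = alpha, eps = eps, beta = beta, m = m, W = W, nu = nu, Nk = Nk)
}

# expected emission log-densities under q(mu, Lambda)
vb_elogdens <- function(X, q) {
  d <- ncol(X); K <- length(q$W)
  logB <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    U <- chol(q$W[[k]])
    Elogdet <- mvdigamma(q$nu[k] / 2, d) + d * log(2) + 2 * sum(log(diag(U)))
    Xc <- sweep(X, 2, q$m[k, ])
    quad <- q$nu[k] * rowSums((Xc %*% t(U))^2)
    logB[, k] <- 0.5 * (Elogdet - d * log(2 * pi) - d / q$beta[k] - quad)
  }
  logB
}

vb_estep <- function(X, q, run_starts, pr) {
  K <- length(q$W)
  logB <- vb_elogdens(X, q)
  lpi <- digamma(q$alpha) - digamma(sum(q$alpha))
  lA <- digamma(q$eps) - digamma(rowSums(q$eps))
  fb <- fb_pass(logB, exp(lpi), matrix(exp(lA), K, K), as.integer(run_starts))
  kl <- kl_dirichlet(q$alpha, pr$alpha0)
  for (j in seq_len(K)) kl <- kl + kl_dirichlet(q$eps[j, ], pr$eps0)
  for (k in seq_len(K)) {
    kl <- kl + kl_normal_wishart(q$m[k, ], q$beta[k], q$W[[k]], q$nu[k],
                                 pr$m0, pr$beta0, pr$W0, pr$nu0)
  }
  fb$elbo <- fb$loglik - kl
  fb
}

# hard-label initialization -> sufficient statistics
init_stats_from_labels <- function(z, K, run_starts, Ttot) {
  gamma <- matrix(0, Ttot, K)
  gamma[cbind(seq_len(Ttot), z)] <- 1
  gamma_init <- numeric(K)
  xi_sum <- matrix(0, K, K)
  ends <- c(run_starts[-1] - 1, Ttot)
  for (r in seq_along(run_starts)) {
    s <- run_starts[r]; e <- ends[r]
    gamma_init[z[s]] <- gamma_init[z[s]] + 1
    if (e > s) {
      tr <- table(factor(z[s:(e - 1)], levels = 1:K),
                  factor(z[(s + 1):e], levels = 1:K))
      xi_sum <- xi_sum + unclass(tr)
    }
  }
  list(gamma = gamma, xi_sum = xi_sum, gamma_init = gamma_init)
}

# ELBO-guided merge pass: propose merging the two closest states (smallest
# symmetrized KL of their posterior-mean Gaussians), re-converge, keep the
# merged model only if the bound improves. Repeats until no merge helps.
# This resolves the classic local optimum where one true state is covered by
# two fitted components that usage-based pruning cannot remove.
merge_pass <- function(X, best, run_starts, pr, max_iter, tol, d) {
  repeat {
    K <- length(best$q$alpha)
    if (K <= 1L) return(best)
    means <- best$q$m
    covs <- lapply(seq_len(K), function(k) {
      chol2inv(chol(best$q$W[[k]])) / (best$q$nu[k] - d - 1)
    })
    div <- matrix(Inf, K, K)
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        a <- brain_state(i, means[i, ], ensure_pd(covs[[i]]))
        b <- brain_state(j, means[j, ], ensure_pd(covs[[j]]))
        div[i, j] <- gaussian_kld(a, b)$jeffreys
      }
    }
    ij <- arrayInd(which.min(div), dim(div))
    i <- ij[1]; j <- ij[2]
    fb <- best$fb
    gamma <- fb$gamma
    gamma[, i] <- gamma[, i] + gamma[, j]
    gamma <- gamma[, -j, drop = FALSE]
    gi <- as.numeric(fb$gamma_init)
    gi[i] <- gi[i] + gi[j]; gi <- gi[-j]
    xs <- fb$xi_sum
    xs[i, ] <- xs[i, ] + xs[j, ]
    xs[, i] <- xs[, i] + xs[, j]
    xs <- xs[-j, -j, drop = FALSE]
    q2 <- vb_mstep(X, gamma, xs, gi, pr)
    cand <- run_vbem(X, q2, run_starts, pr, max_iter, tol)
    if (cand$fb$elbo > best$fb$elbo) {
      cand$restart <- best$restart
      cand$history <- c(best$history, cand$trace)
      best <- cand
    } else {
      return(best)
    }
  }
}

run_vbem <- function(X, q, run_starts, pr, max_iter, tol) {
  trace <- numeric(0)
  fb <- NULL
  for (it in seq_len(max_iter)) {
    fb <- vb_estep(X, q, run_starts, pr)
    trace <- c(trace, fb$elbo)
    if (it > 1L) {
      rel <- abs(trace[it] - trace[it - 1]) / max(1, abs(trace[it]))
      if (rel < tol) break
    }
    q <- vb_mstep(X, fb$gamma, fb$xi_sum, fb$gamma_init, pr)
  }
  list(q = q, fb = fb, trace = trace)
}

# ---- user-facing model fitting --------------------------------------------

#' Fit a variational-Bayes hidden Markov brain-state model
#'
#' Fits one group-level Gaussian-emission HMM across all supplied runs
#' (concatenated, with the Markov chain restarting at every run boundary) by
#' variational Bayes EM. Sparse Dirichlet priors on the initial probabilities
#' and on each transition row act as an automatic-relevance-determination
#' mechanism: after convergence, states whose expected usage falls below
#' `prune_threshold` are removed and the model is re-converged, so the
#' effective number of states is learned from the data starting from a
#' deliberately over-complete `K_init`. A final ELBO-guided merge pass
#' proposes fusing the two closest surviving states and keeps the merge only
#' when the bound improves, eliminating duplicate components that split one
#' true state (a local optimum usage-based pruning cannot escape).
#'
#' @param runs list of [roi_ts()] sharing ROI labels; total timepoints must
#'   be at least `10 * K_init`.
#' @param K_init initial number of candidate states (default 15).
#' @param n_restarts k-means initializations tried; the best evidence lower
#'   bound (ELBO) wins.
#' @param max_iter,tol VB iteration cap and relative-ELBO convergence
#'   tolerance.
#' @param prune_threshold minimum expected usage (fraction of total time) a
#'   state must attain to survive; default `1 / (10 * K_init)`.
#' @param seed integer seed controlling the k-means initializations; the fit
#'   is deterministic given `seed`.
#' @param priors optional list overriding elements of the default priors
#'   (`alpha0`, `eps0`, `beta0`, `m0`, `nu0`, `W0`).
#' @return An object of class `state_model` with elements `K` (effective
#'   state count), `initial_probs`, `transition`, `states` (per-state mean
#'   and covariance), `ard_weights` (expected usage), `elbo`, `elbo_trace`,
#'   the full variational `posterior`, and `posteriors` — one
#'   `state_posterior` (T x K temporal posterior probability matrix) per run.
#' @export
fit_state_model <- function(runs, K_init = 15L, n_restarts = 5L,
                            max_iter = 500L, tol = 1e-6,
                            prune_threshold = 1 / (10 * K_init),
                            seed = 1L, priors = list()) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  labs <- runs[[1]]$roi_labels
  for (r in runs) {
    stopifnot(inherits(r, "roi_ts"))
    if (!identical(r$roi_labels, labs)) stop("ROI labels differ across runs")
    if (any(!is.finite(r$values))) stop("non-finite values in input runs")
  }
  X <- do.call(rbind, lapply(runs, function(r) r$values))
  Tn <- vapply(runs, function(r) nrow(r$values), integer(1))
  if (sum(Tn) < 10 * K_init) stop("need at least 10 * K_init total timepoints")
  run_starts <- cumsum(c(1L, Tn[-length(Tn)]))
  d <- ncol(X)
  pr <- utils::modifyList(default_priors(d), priors)

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    z <- with_seed(derive_seed(seed, 5, rs), {
      km <- suppressWarnings(stats::kmeans(X, centers = min(K_init, nrow(X)),
                                           iter.max = 100, nstart = 1))
      km$cluster
    })
    st <- init_stats_from_labels(z, K_init, run_starts, nrow(X))
    q <- vb_mstep(X, st$gamma, st$xi_sum, st$gamma_init, pr)
    fit <- run_vbem(X, q, run_starts, pr, max_iter, tol)
    if (is.null(best) || fit$fb$elbo > best$fb$elbo) {
      best <- fit
      best$restart <- rs
    }
  }

  # ARD pruning: drop under-used states, re-converge, repeat until stable;
  # then ELBO-guided merges to resolve duplicate-component local optima
  best$history <- best$trace
  repeat {
    usage <- colSums(best$fb$gamma) / nrow(X)
    keep <- usage >= prune_threshold
    if (all(keep)) break
    if (!any(keep)) stop("all states pruned; lower `prune_threshold`")
    q <- best$q
    q$alpha <- q$alpha[keep]
    q$eps <- q$eps[keep, keep, drop = FALSE]
    q$beta <- q$beta[keep]
    q$m <- q$m[keep, , drop = FALSE]
    q$W <- q$W[keep]
    q$nu <- q$nu[keep]
    refit <- run_vbem(X, q, run_starts, pr, max_iter, tol)
    refit$restart <- best$restart
    refit$history <- c(best$history, refit$trace)
    best <- refit
  }
  best <- merge_pass(X, best, run_starts, pr, max_iter, tol, d)
  trace <- best$trace

  q <- best$q
  K <- length(q$alpha)
  usage <- colSums(best$fb$gamma) / nrow(X)
  states <- lapply(seq_len(K), function(k) {
    cov <- chol2inv(chol(q$W[[k]])) / (q$nu[k] - d - 1)
    cov <- (cov + t(cov)) / 2
    dimnames(cov) <- list(labs, labs)
    brain_state(state_id = k, mean = stats::setNames(q$m[k, ], labs),
                cov = cov, roi_labels = labs)
  })
  tpp <- split_posteriors(best$fb$gamma, runs, Tn)
  structure(
    list(K = K, K_init = as.integer(K_init),
         initial_probs = q$alpha / sum(q$alpha),
         transition = q$eps / rowSums(q$eps),
         states = states, roi_labels = labs,
         ard_weights = usage, elbo = best$fb$elbo, elbo_trace = trace,
         elbo_history = best$history,
         seed = as.integer(seed), restart_best = best$restart,
         n_restarts = as.integer(n_restarts),
         prune_threshold = prune_threshold, priors = pr,
         posterior = q, posteriors = tpp,
         schema_version = 1L),
    class = "state_model")
}

split_posteriors <- function(gamma, runs, Tn) {
  out <- vector("list", length(runs))
  names(out) <- names(runs)
  off <- 0L
  for (i in seq_along(runs)) {
    out[[i]] <- state_posterior(gamma[(off + 1):(off + Tn[i]), , drop = FALSE],
                                subject_id = runs[[i]]$subject_id,
                                task_id = runs[[i]]$task_id,
                                run_id = runs[[i]]$run_id)
    off <- off + Tn[i]
  }
  out
}

#' Per-state Gaussian ("brain state") container
#'
#' @param state_id integer state index.
#' @param mean D-vector of state mean activation (z-units).
#' @param cov D x D symmetric positive-definite covariance ("functional
#'   connectivity").
#' @param roi_labels ROI names.
#' @return An object of class `brain_state`.
#' @export
brain_state <- function(state_id, mean, cov, roi_labels = names(mean)) {
  stopifnot(length(mean) == nrow(cov), nrow(cov) == ncol(cov))
  if (max(abs(cov - t(cov))) > 1e-8) stop("covariance must be symmetric")
  structure(list(state_id = state_id, mean = mean, cov = ensure_pd(cov),
                 roi_labels = roi_labels),
            class = "brain_state")
}

#' Temporal posterior probability container
#'
#' @param tpp T x K matrix; rows must sum to 1.
#' @param subject_id,task_id,run_id run identifiers.
#' @return An object of class `state_posterior`.
#' @export
state_posterior <- function(tpp, subject_id = NA_character_,
                            task_id = NA_character_, run_id = NA_character_) {
  tpp <- as.matrix(tpp)
  if (any(tpp < -1e-8) || max(abs(rowSums(tpp) - 1)) > 1e-6) {
    stop("TPP rows must be probabilities summing to 1")
  }
  structure(list(tpp = tpp, subject_id = subject_id, task_id = task_id,
                 run_id = run_id), class = "state_posterior")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> K = %d (from K_init = %d), D = %d, ELBO = %.2f\n",
              x$K, x$K_init, length(x$roi_labels), x$elbo))
  cat("  usage:", paste(sprintf("%.3f", x$ard_weights), collapse = " "), "\n")
  invisible(x)
}

#' Transfer a fitted model to new runs
#'
#' Holds the global latent variables fixed — initial probabilities,
#' transition matrix and per-state Gaussians — and computes the local
#' temporal posterior probabilities on new data by a single exact
#' forward-backward pass per run. This is the transfer mechanism behind
#' state temporal closeness: a reference task's states can be tracked in any
#' other task's data.
#'
#' @param model a [fit_state_model()] result.
#' @param runs list of [roi_ts()] with the model's ROI labels.
#' @return Named list of `state_posterior`, one per run.
#' @export
apply_state_model <- function(model, runs) {
  stopifnot(inherits(model, "state_model"))
  out <- vector("list", length(runs))
  names(out) <- names(runs)
  K <- model$K
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    stopifnot(inherits(r, "roi_ts"))
    if (!identical(r$roi_labels, model$roi_labels)) {
      stop("ROI labels of run ", i, " do not match the model")
    }
    logB <- vapply(seq_len(K), function(k) {
      mvn_logdens(r$values, model$states[[k]]$mean, model$states[[k]]$cov)
    }, numeric(nrow(r$values)))
    fb <- fb_pass(matrix(logB, ncol = K), model$initial_probs,
                  model$transition, 1L)
    out[[i]] <- state_posterior(fb$gamma, subject_id = r$subject_id,
                                task_id = r$task_id, run_id = r$run_id)
  }
  out
}

#' Evidence lower bound of a fitted model on data
#'
#' Evaluates the variational bound (log normalizer of the structured
#' posterior minus the prior KL terms) for the model's current variational
#' posterior on the supplied runs.
#'
#' @inheritParams apply_state_model
#' @return A finite scalar.
#' @export
model_elbo <- function(model, runs) {
  stopifnot(inherits(model, "state_model"))
  X <- do.call(rbind, lapply(runs, function(r) r$values))
  Tn <- vapply(runs, function(r) nrow(r$values), integer(1))
  run_starts <- cumsum(c(1L, Tn[-length(Tn)]))
  vb_estep(X, model$posterior, run_starts, model$priors)$elbo
}

# ---- serialization ---------------------------------------------------------

#' Serialize / deserialize a state model
#'
#' Writes the model (global variables, variational posterior, diagnostics;
#' not the per-run posteriors) as schema-versioned JSON at full numeric
#' precision, and reads it back.
#'
#' @param model a `state_model`.
#' @param path file path.
#' @return `write_state_model()` returns `path` invisibly;
#'   `read_state_model()` returns the `state_model`.
#' @export
write_state_model <- function(model, path) {
  stopifnot(inherits(model, "state_model"))
  obj <- list(
    schema_version = model$schema_version,
    K = model$K, K_init = model$K_init,
    roi_labels = model$roi_labels,
    initial_probs = model$initial_probs,
    transition = unclass(model$transition),
    state_means = lapply(model$states, function(s) unname(s$mean)),
    state_covs = lapply(model$states, function(s) unname(s$cov)),
    ard_weights = model$ard_weights,
    elbo = model$elbo, elbo_trace = model$elbo_trace,
    seed = model$seed, restart_best = model$restart_best,
    n_restarts = model$n_restarts, prune_threshold = model$prune_threshold,
    priors = list(alpha0 = model$priors$alpha0, eps0 = model$priors$eps0,
                  beta0 = model$priors$beta0, m0 = model$priors$m0,
                  nu0 = model$priors$nu0, W0 = unname(model$priors$W0)),
    posterior = list(alpha = model$posterior$alpha,
                     eps = unclass(model$posterior$eps),
                     beta = model$posterior$beta,
                     m = unclass(model$posterior$m),
                     W = lapply(model$posterior$W, unname),
                     nu = model$posterior$nu))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_state_model
#' @export
read_state_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported state_model schema version: ",
         if (is.null(obj$schema_version)) "<missing>" else obj$schema_version)
  }
  labs <- obj$roi_labels
  K <- obj$K
  as_mat_list <- function(x) {
    if (is.list(x)) lapply(x, function(m) matrix(unlist(m), nrow = sqrt(length(unlist(m))))) else
      lapply(seq_len(dim(x)[1]), function(i) matrix(x[i, , ], dim(x)[2], dim(x)[3]))
  }
  covs <- as_mat_list(obj$state_covs)
  means <- obj$state_means
  if (!is.list(means)) means <- lapply(seq_len(nrow(means)), function(i) means[i, ])
  states <- lapply(seq_len(K), function(k) {
    brain_state(k, stats::setNames(as.numeric(means[[k]]), labs),
                structure(covs[[k]], dimnames = list(labs, labs)), labs)
  })
  transition <- matrix(unlist(obj$transition), K, K)
  pr <- obj$priors
  pr$m0 <- as.numeric(pr$m0)
  pr$W0 <- matrix(unlist(pr$W0), length(pr$m0), length(pr$m0))
  post <- obj$posterior
  q <- list(alpha = as.numeric(post$alpha),
            eps = matrix(unlist(post$eps), K, K),
            beta = as.numeric(post$beta),
            m = matrix(unlist(post$m), K, length(labs)),
            W = as_mat_list(post$W),
            nu = as.numeric(post$nu))
  structure(
    list(K = K, K_init = obj$K_init,
         initial_probs = as.numeric(obj$initial_probs),
         transition = transition, states = states, roi_labels = labs,
         ard_weights = as.numeric(obj$ard_weights), elbo = obj$elbo,
         elbo_trace = as.numeric(obj$elbo_trace), seed = obj$seed,
         restart_best = obj$restart_best, n_restarts = obj$n_restarts,
         prune_threshold = obj$prune_threshold, priors = pr,
         posterior = q, posteriors = NULL, schema_version = 1L),
    class = "state_model")
}
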