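# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Textbook alpha-beta recursion (log-free, scaled), one run, for checking
# posterior state probabilities against the package's forward-backward.
oracle_forward_backward <- function(B, pi, A) {
  # B: T x K plain emission likelihoods (not logs)
  T_ <- nrow(B); K <- ncol(B)
  alpha <- matrix(0, T_, K); beta <- matrix(0, T_, K); cv <- numeric(T_)
  alpha[1, ] <- pi * B[1, ]
  cv[1] <- sum(alpha[1, ]); alpha[1, ] <- alpha[1, ] / cv[1]
  for (t in 2:T_) {
    alpha[t, ] <- (alpha[t - 1, ] %*% A) * B[t, ]
    cv[t] <- sum(alpha[t, ]); alpha[t, ] <- alpha[t, ] / cv[t]
  }
  beta[T_, ] <- 1
  for (t in (T_ - 1):1) {
    beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cv[t + 1]
  }
  g <- alpha * beta
  g / rowSums(g)
}

# Plain multivariate normal log-density (row-wise), coded independently of
# the package's chol-based version: solve() route.
oracle_mvn_logdens <- function(X, m, S) {
  d <- ncol(X)
  Si <- solve(S)
  Xc <- sweep(X, 2, m)
  -0.5 * (d * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus[1] +
            rowSums((Xc %*% Si) * Xc))
}

# Monte-Carlo KL(N_a || N_b) by sample-average log-density ratio.
oracle_mc_kl <- function(mean_a, cov_a, mean_b, cov_b, n = 1e6) {
  d <- length(mean_a)
  L <- chol(cov_a)
  Z <- matrix(rnorm(n * d), n, d) %*% L
  X <- sweep(Z, 2, mean_a, "+")
  mean(oracle_mvn_logdens(X, mean_a, cov_a) - oracle_mvn_logdens(X, mean_b, cov_b))
}

# Exact log marginal likelihood of i.i.d. Gaussian data under a
# Normal-Wishart prior, via sequential Student-t one-step predictives
# (independent of any evidence formula used elsewhere).
oracle_nw_evidence <- function(X, m0, beta0, W0, nu0) {
  d <- ncol(X)
  m <- m0; beta <- beta0; nu <- nu0; Winv <- solve(W0)
  ll <- 0
  mvt_logdens <- function(x, df, mu, Sigma) {
    p <- length(x)
    dm <- x - mu
    q <- drop(crossprod(dm, solve(Sigma, dm)))
    lgamma((df + p) / 2) - lgamma(df / 2) - (p / 2) * log(df * pi) -
      0.5 * determinant(Sigma, logarithm = TRUE)$modulus[1] -
      ((df + p) / 2) * log1p(q / df)
  }
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    df <- nu - d + 1
    Sig <- Winv * (beta + 1) / (beta * df)
    ll <- ll + mvt_logdens(x, df, m, Sig)
    # conjugate update
    Winv <- Winv + (beta / (beta + 1)) * tcrossprod(x - m)
    m <- (beta * m + x) / (beta + 1)
    beta <- beta + 1
    nu <- nu + 1
  }
  ll
}

# Stationary distribution via left eigenvector of A (eigen route, not the
# package's power iteration).
oracle_stationary <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# Brute-force alignment of true states to fitted states by total symmetrized
# KL over all injective maps (true index -> fitted index).
align_states <- function(true_states, fitted_states) {
  kt <- length(true_states); kf <- length(fitted_states)
  D <- outer(seq_len(kt), seq_len(kf), Vectorize(function(i, j) {
    gaussian_kld(true_states[[i]], fitted_states[[j]])$jeffreys
  }))
  idx <- expand.grid(rep(list(seq_len(kf)), kt))
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == kt), , drop = FALSE]
  v <- apply(idx, 1, function(r) sum(D[cbind(seq_len(kt), as.integer(r))]))
  as.integer(idx[which.min(v), ])
}

# brain_state objects for a task's ground-truth states
truth_states <- function(truth, task) {
  K <- nrow(truth$state_means[[task]])
  lapply(seq_len(K), function(k) {
    brain_state(k, truth$state_means[[task]][k, ],
                truth$state_covs[[task]][[k]], truth$roi_labels)
  })
}

# index of the fitted state closest to the planted shared state
planted_state_in <- function(model, truth, task) {
  s <- truth$shared_state_id[[task]]
  tb <- brain_state(s, truth$state_means[[task]][s, ],
                    truth$state_covs[[task]][[s]], truth$roi_labels)
  which.min(vapply(model$states, function(st) gaussian_kld(tb, st)$jeffreys,
                   numeric(1)))
}

# small random PD matrix for tests (independent of the package's sampler)
rand_cov_test <- function(d) {
  M <- matrix(rnorm(d * (d + 3)), d + 3, d)
  crossprod(M) / (d + 3)
}
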