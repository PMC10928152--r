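# internal numerical helpers

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seeds, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 7919 + as.double(i) * 104729 + 13) %% 2147483647
  as.integer(s) + 1L
}

# Stationary distribution of a row-stochastic matrix by power iteration.
stationary_dist <- function(A, tol = 1e-12, max_iter = 10000L) {
  K <- nrow(A)
  p <- rep(1 / K, K)
  for (i in seq_len(max_iter)) {
    p2 <- as.vector(p %*% A)
    p2 <- p2 / sum(p2)
    if (max(abs(p2 - p)) < tol) return(p2)
    p <- p2
  }
  p
}

# Draw n samples from N(mean, cov) via Cholesky.
rmvnorm_chol <- function(n, mean, cov) {
  d <- length(mean)
  L <- chol(cov)                 # upper: cov = t(L) %*% L
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% L, 2, mean, "+")
}

# Random symmetric positive-definite covariance with variances near 1.
rand_pd_cov <- function(d, df = d + 5L) {
  W <- drop(stats::rWishart(1, df, diag(d) / df))
  s <- sqrt(diag(W))
  C <- W / tcrossprod(s)                       # correlation matrix
  v <- stats::runif(d, 0.7, 1.3)
  C * tcrossprod(sqrt(v))
}

logdet <- function(S) {
  2 * sum(log(diag(chol(S))))
}

# Gaussian log-density for all rows of X (T x D), via Cholesky.
mvn_logdens <- function(X, mean, cov) {
  d <- ncol(X)
  U <- chol(cov)
  Xc <- sweep(X, 2, mean)
  q <- rowSums((Xc %*% backsolve(U, diag(d)))^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + q)
}

# Symmetrize and, if needed, jitter a covariance to positive definiteness.
ensure_pd <- function(S, rel = 1e-6) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    S <- S + diag(rel * sum(diag(S)) / nrow(S), nrow(S))
  }
  S
}
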