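#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Scaled forward-backward over concatenated runs with chain resets.
//
// log_b: T x K matrix of (expected) emission log-densities.
// pi, A: initial and transition weights; may be unnormalised subprobabilities
//        (exp of Dirichlet expected-log parameters), in which case the
//        returned loglik is the variational log-normaliser.
// run_starts: 1-based start index of each run; chains restart at each.
//
// Returns gamma (T x K, rows sum to 1), xi_sum (K x K, summed two-slice
// marginals over within-run transitions), gamma_init (K, summed first-frame
// posteriors across runs) and loglik.
// [[Rcpp::export]]
Rcpp::List fb_pass(const arma::mat& log_b, const arma::vec& pi,
                   const arma::mat& A, const arma::ivec& run_starts) {
  const uword T = log_b.n_rows, K = log_b.n_cols;
  const uword R = run_starts.n_elem;
  mat gamma(T, K, fill::zeros);
  mat xi_sum(K, K, fill::zeros);
  vec gamma_init(K, fill::zeros);
  double loglik = 0.0;

  mat At = A.t();
  mat alpha(T, K);          // scaled forward messages
  vec cvec(T);              // scaling constants
  vec shift(T);             // per-frame max-shift of log_b
  mat b(T, K);              // shifted emission likelihoods

  for (uword t = 0; t < T; ++t) {
    double m = log_b.row(t).max();
    shift(t) = m;
    b.row(t) = exp(log_b.row(t) - m);
  }

  for (uword r = 0; r < R; ++r) {
    uword s = (uword)(run_starts(r) - 1);
    uword e = (r + 1 < R) ? (uword)(run_starts(r + 1) - 2) : T - 1;

    // forward
    rowvec a = (pi.t() % b.row(s));
    double c = accu(a);
    if (c <= 0) Rcpp::stop("forward pass underflow at run start");
    a /= c;
    alpha.row(s) = a;
    cvec(s) = c;
    loglik += std::log(c) + shift(s);
    for (uword t = s + 1; t <= e; ++t) {
      a = (a * A) % b.row(t);
      c = accu(a);
      if (c <= 0) Rcpp::stop("forward pass underflow");
      a /= c;
      alpha.row(t) = a;
      cvec(t) = c;
      loglik += std::log(c) + shift(t);
    }

    // backward + marginals
    rowvec beta(K, fill::ones);
    gamma.row(e) = alpha.row(e);
    for (uword t = e; t > s; --t) {
      rowvec bb = b.row(t) % beta;             // K
      // two-slice marginal for t-1 -> t
      mat xi = (alpha.row(t - 1).t() * bb) % A / cvec(t);
      xi_sum += xi;
      beta = (A * bb.t()).t() / cvec(t);
      gamma.row(t - 1) = alpha.row(t - 1) % beta;
      double g = accu(gamma.row(t - 1));
      gamma.row(t - 1) /= g;                   // guard tiny drift
    }
    gamma_init += gamma.row(s).t();
  }

  return Rcpp::List::create(
    Rcpp::Named("gamma") = gamma,
    Rcpp::Named("xi_sum") = xi_sum,
    Rcpp::Named("gamma_init") = gamma_init,
    Rcpp::Named("loglik") = loglik);
}
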