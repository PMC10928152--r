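bs <- function(mean, cov, labels = paste0("R", seq_along(mean)), id = 1) {
  brain_state(id, mean, cov, labels)
}

test_that("Gaussian KL has its closed-form values", {
  # identical Gaussians
  S <- rand_cov_test(3)
  a <- bs(c(0, 1, -1), S)
  expect_equal(gaussian_kld(a, a)$jeffreys, 0)
  # 1-D is blocked by the D >= 2 container, so use the 2-D product form:
  # independent N(0,1) x N(0,1) vs N(1,1) x N(0,1) => KL = 0.5 each way
  a2 <- bs(c(0, 0), diag(2))
  b2 <- bs(c(1, 0), diag(2))
  kl <- gaussian_kld(a2, b2)
  expect_equal(kl$kl_ab, 0.5)
  expect_equal(kl$kl_ba, 0.5)
  expect_equal(kl$jeffreys, 1.0)
  expect_equal(state_space_closeness(a2, b2)$c, 1.0)
  expect_error(gaussian_kld(a2, bs(c(0, 0), diag(2), c("X", "Y"))),
               "different ROI sets")
})

test_that("closed-form KL agrees with Monte-Carlo sampling", {
  set.seed(41)
  for (i in 1:3) {
    ma <- rnorm(4); mb <- rnorm(4)
    Sa <- rand_cov_test(4); Sb <- rand_cov_test(4)
    kl <- gaussian_kld(bs(ma, Sa), bs(mb, Sb))$kl_ab
    mc <- oracle_mc_kl(ma, Sa, mb, Sb, n = 2e5)
    expect_lt(abs(kl - mc), 0.02 * max(kl, 1))
  }
})

test_that("closeness inverts divergence and is rotation-consistent", {
  set.seed(42)
  a <- bs(rnorm(4), rand_cov_test(4))
  cands <- lapply(1:3, function(i) bs(rnorm(4), rand_cov_test(4)))
  cs <- vapply(cands, function(b) state_space_closeness(a, b)$c, numeric(1))
  dv <- vapply(cands, function(b) state_space_closeness(a, b)$divergence_value,
               numeric(1))
  expect_equal(order(cs), rev(order(dv)))
  # identical pair: infinite closeness, flagged
  self <- state_space_closeness(a, a)
  expect_true(is.infinite(self$c))
  expect_true(self$infinite)
  # joint orthogonal rotation leaves closeness unchanged
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  rot <- function(s) bs(drop(Q %*% s$mean), Q %*% s$cov %*% t(Q),
                        s$roi_labels)
  b <- cands[[1]]
  expect_equal(state_space_closeness(rot(a), rot(b))$c,
               state_space_closeness(a, b)$c, tolerance = 1e-8)
})

test_that("temporal closeness has its trivial structure", {
  set.seed(43)
  T_ <- 60
  p1 <- runif(T_, 0.05, 0.95)
  tppA <- cbind(p1, 1 - p1)
  spA <- state_posterior(tppA, subject_id = "s1")
  tc_self <- temporal_closeness_matrix(list(spA), list(spA))
  expect_equal(diag(tc_self$r), c(1, 1), tolerance = 1e-12)
  # complementarity for two-state targets: r(., 1) = -r(., 2)
  p2 <- runif(T_, 0.05, 0.95)
  spB <- state_posterior(cbind(p2, 1 - p2), subject_id = "s1")
  tc <- temporal_closeness_matrix(list(spA), list(spB))
  expect_equal(tc$r[, 1], -tc$r[, 2], tolerance = 1e-12)
  # never-visited state yields a flagged undefined correlation
  spC <- state_posterior(cbind(rep(1, T_), rep(0, T_)), subject_id = "s1")
  tcc <- temporal_closeness_matrix(list(spA), list(spC))
  expect_true(all(is.na(tcc$r[, 1])))
  expect_true(all(tcc$undefined[, 1]))
})

test_that("permutation p-values count exceedances with a floor", {
  expect_equal(perm_count <- mdstates:::perm_pvalue(0.5, c(rep(1, 30), rep(0, 70)),
                                                    100)$p_value, 0.30)
  fl <- mdstates:::perm_pvalue(2, rep(1, 100), 100)
  expect_equal(fl$p_value, 0.01)
  expect_true(fl$floored)
  expect_match(fl$p_label, "<")
})

test_that("an identical observed pair is maximally significant", {
  set.seed(44)
  mk_model <- function(K, d = 4, seed = 1) {
    set.seed(seed)
    states <- lapply(seq_len(K), function(k) bs(rnorm(d), rand_cov_test(d),
                                                id = k))
    structure(list(K = K, states = states, roi_labels = states[[1]]$roi_labels),
              class = "state_model")
  }
  m1 <- mk_model(4, seed = 45)
  m2 <- mk_model(4, seed = 46)
  m2$states[[2]] <- m1$states[[3]]        # plant an exact replica
  obs <- state_space_closeness(m1$states[[3]], m2$states[[2]])$c
  p <- permutation_p_space(list(ref = m1, target = m2),
                           list(c("ref", 3), c("target", 2)), obs,
                           n_perm = 100, seed = 9)
  expect_true(p$floored)
  expect_equal(p$p_value, 0.01)
  expect_length(p$null_samples, 100)
})

test_that("null-pair permutation p-values are calibrated (reduced run)", {
  set.seed(47)
  pvals <- replicate(150, {
    states <- lapply(1:8, function(k) bs(rnorm(4), rand_cov_test(4), id = k))
    m1 <- structure(list(K = 4, states = states[1:4],
                         roi_labels = states[[1]]$roi_labels),
                    class = "state_model")
    m2 <- structure(list(K = 4, states = states[5:8],
                         roi_labels = states[[1]]$roi_labels),
                    class = "state_model")
    i <- sample(1:4, 1); j <- sample(1:4, 1)
    obs <- state_space_closeness(m1$states[[i]], m2$states[[j]])$c
    permutation_p_space(list(a = m1, b = m2),
                        list(c("a", i), c("b", j)), obs, n_perm = 50,
                        seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("match_states is a self-match fixed point and reports consistency", {
  sr_truth <- simulate_ground_truth(tasks = "a", n_states = 3,
                                    roi_labels = paste0("R", 1:4),
                                    n_subjects = 4, shared = FALSE, seed = 48)
  ds <- generate_task_dataset(sr_truth, "a", 4, 150)
  m <- fit_state_model(ds$runs, K_init = 5, n_restarts = 2, seed = 7)
  rep_self <- match_states(2, m, m, ds$runs, n_perm = 30, seed = 1)
  expect_equal(rep_self$matched_state_id, 2L)
  expect_true(rep_self$consistent)
  expect_true(is.infinite(rep_self$candidates$c[2]))  # exact self-pair
  # report writers
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_match_report(rep_self, jp, tp)
  expect_true(file.exists(jp) && file.exists(tp))
  tab <- read.delim(tp)
  expect_equal(nrow(tab), m$K)
  unlink(c(jp, tp))
})

test_that("a planted shared state is matched consistently by both metrics", {
  cfg <- sim_config(n_subjects = 8, n_timepoints = 150, n_states = 3,
                    seed = 49)
  co <- generate_multitask_cohort(cfg)
  mr <- fit_state_model(co$runs$nback, K_init = 6, n_restarts = 2, seed = 11)
  mt <- fit_state_model(co$runs$axcpt, K_init = 6, n_restarts = 2, seed = 12)
  rs <- planted_state_in(mr, co$truth, "nback")
  planted <- planted_state_in(mt, co$truth, "axcpt")
  rep_m <- match_states(rs, mr, mt, co$runs$axcpt, n_perm = 50, seed = 2)
  expect_equal(rep_m$matched_state_id, planted)
  expect_true(rep_m$consistent)
  expect_lte(rep_m$p_space$p_value, 0.05)
})
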