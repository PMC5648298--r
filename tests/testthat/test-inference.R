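# Variational updates, ELBO behaviour, and invariants of the fit loop.

test_that("initial responsibilities are normalized, reproducible and degenerate-safe", {
  b <- tiny_gaussian_bundle(n = 6, d = 3, seed = 1)
  set.seed(11); r1 <- mcoclust:::init_responsibilities(b, 3, 2, 4)
  set.seed(11); r2 <- mcoclust:::init_responsibilities(b, 3, 2, 4)
  expect_identical(r1, r2)
  expect_equal(rowSums(r1$tau$gaussian), rep(1, 3), tolerance = 1e-10)
  for (v in 1:3) expect_equal(rowSums(r1$eta[, , v]), rep(1, 6), tolerance = 1e-10)
  r3 <- mcoclust:::init_responsibilities(b, 1, 1, 1)
  expect_equal(as.vector(r3$tau$gaussian), rep(1, 3))
  expect_equal(as.vector(r3$eta), rep(1, 6))
})

test_that("stick posterior updates equal the scalar closed-form sums", {
  b <- mixed_bundle(n = 7, seed = 5)
  prior <- mcc_prior(alpha1 = 1.3, alpha2 = 0.8, beta_obj = 2.1)
  V <- 3; G <- 2; K <- 2
  resp <- random_resp(b, V, G, K, seed = 6)
  got <- mcoclust:::update_stick_posteriors(resp, prior, V, G, K)
  ref <- oracle_update_sticks(resp, prior, V, G, K)
  expect_equal(got$view$g1, ref$view$g1, tolerance = 1e-12)
  expect_equal(got$view$g2, ref$view$g2, tolerance = 1e-12)
  for (m in names(got$feat)) {
    expect_equal(got$feat[[m]]$g1, ref$feat[[m]]$g1, tolerance = 1e-12)
    expect_equal(got$feat[[m]]$g2, ref$feat[[m]]$g2, tolerance = 1e-12)
  }
  expect_equal(got$obj$g1, ref$obj$g1, tolerance = 1e-12)
  expect_equal(got$obj$g2, ref$obj$g2, tolerance = 1e-12)
  # conservation: view stick masses account for every feature
  expect_equal(sum(got$view$g1 - 1), b$d_total, tolerance = 1e-10)
})

test_that("concentrated and uniform responsibilities give the expected sticks", {
  b <- tiny_gaussian_bundle(n = 4, d = 5, seed = 2)
  V <- 2; G <- 2; K <- 2
  resp <- random_resp(b, V, G, K, seed = 1)
  # all feature mass in view 1, cluster 1
  resp$tau$gaussian[] <- 0; resp$tau$gaussian[, 1] <- 1
  st <- mcoclust:::update_stick_posteriors(resp, mcc_prior(), V, G, K)
  expect_equal(st$view$g1[1], 1 + 5)
  expect_equal(st$view$g2[1], 1)   # alpha1 = 1, no mass beyond view 1
  # uniform tau: view sticks identical across views
  resp$tau$gaussian[] <- 1 / (G * V)
  st <- mcoclust:::update_stick_posteriors(resp, mcc_prior(), V, G, K)
  expect_equal(st$view$g1[1], st$view$g1[2])
})

test_that("responsibility updates equal the scalar brute-force evaluation", {
  for (case in 1:3) {
    b <- if (case == 3) mixed_bundle(n = 4, seed = case)
         else tiny_gaussian_bundle(n = 4, d = 2, seed = case,
                                   missing = ifelse(case == 2, 0.3, 0))
    V <- 2; G <- 2; K <- 2
    prior <- mcc_prior()
    resp <- random_resp(b, V, G, K, seed = 10 + case)
    stats_list <- lapply(b$families, function(s)
      mcoclust:::family_stats(s$X, s$mask, s$family, s$n_levels))
    U <- lapply(names(b$families), function(m)
      mcoclust:::compute_U(stats_list[[m]], resp$eta, V))
    names(U) <- names(b$families)
    blocks <- mcoclust:::update_blocks(b, stats_list, U, resp, prior, V, G, K)
    sticks <- mcoclust:::update_stick_posteriors(resp, prior, V, G, K)

    tau_new <- mcoclust:::update_tau(b, stats_list, U, sticks, blocks, V, G, K)
    tau_ref <- oracle_update_tau(b, resp$eta, sticks, blocks, V, G, K)
    for (m in names(tau_new))
      expect_equal(tau_new[[m]], tau_ref[[m]], tolerance = 1e-10,
                   ignore_attr = TRUE)

    eta_new <- mcoclust:::update_eta(b, stats_list, tau_new, sticks, blocks, V, G, K)
    eta_ref <- oracle_update_eta(b, tau_new, sticks, blocks, V, G, K)
    expect_equal(eta_new$eta, eta_ref, tolerance = 1e-10)
  }
})

test_that("single-cluster truncations give unit responsibilities", {
  b <- tiny_gaussian_bundle(n = 4, d = 2, seed = 4)
  prior <- mcc_prior()
  resp <- random_resp(b, 1, 1, 1, seed = 2)
  stats_list <- lapply(b$families, function(s)
    mcoclust:::family_stats(s$X, s$mask, s$family, s$n_levels))
  U <- list(gaussian = mcoclust:::compute_U(stats_list$gaussian, resp$eta, 1))
  blocks <- mcoclust:::update_blocks(b, stats_list, U, resp, prior, 1, 1, 1)
  sticks <- mcoclust:::update_stick_posteriors(resp, prior, 1, 1, 1)
  tau <- mcoclust:::update_tau(b, stats_list, U, sticks, blocks, 1, 1, 1)
  expect_equal(as.vector(tau$gaussian), rep(1, 2))
  eta <- mcoclust:::update_eta(b, stats_list, tau, sticks, blocks, 1, 1, 1)
  expect_equal(as.vector(eta$eta), rep(1, 4))
})

test_that("ELBO is non-decreasing across sweeps on random small instances", {
  worst <- 0
  for (seed in 1:100) {
    b <- tiny_gaussian_bundle(n = 5, d = 3, seed = seed,
                              missing = ifelse(seed %% 3 == 0, 0.2, 0))
    res <- fit_small(b, V = 2, G = 2, K = 2, seed = 1000 + seed, sweeps = 12)
    dif <- diff(res$trace)
    worst <- min(worst, min(dif))
    expect_gte(min(dif), -1e-8)
  }
  expect_gte(worst, -1e-8)
})

test_that("ELBO stays below the exact truncated-model log marginal", {
  set.seed(31)
  X <- matrix(rnorm(6, mean = rep(c(0, 2), each = 3)), 3, 2)
  b <- mcc_bundle(as.data.frame(X), "gaussian", standardize = FALSE)
  prior <- mcc_prior()
  bound <- oracle_log_marginal(X, prior)
  for (seed in 1:5) {
    res <- fit_small(b, V = 2, G = 2, K = 2, seed = seed, sweeps = 80)
    expect_lte(res$elbo, bound + 1e-6)
  }
  # and the optimized bound should be reasonably tight on this tiny instance
  expect_gt(max(sapply(1:5, function(seed)
    fit_small(b, 2, 2, 2, seed, 80)$elbo)), bound - 5)
})

test_that("fast in-sweep ELBO equals the standalone recomputation", {
  b <- mixed_bundle(n = 6, seed = 9)
  V <- 2; G <- 2; K <- 3
  prior <- mcc_prior()
  resp <- random_resp(b, V, G, K, seed = 3)
  stats_list <- lapply(b$families, function(s)
    mcoclust:::family_stats(s$X, s$mask, s$family, s$n_levels))
  U <- lapply(names(b$families), function(m)
    mcoclust:::compute_U(stats_list[[m]], resp$eta, V))
  names(U) <- names(b$families)
  blocks <- mcoclust:::update_blocks(b, stats_list, U, resp, prior, V, G, K)
  sticks <- mcoclust:::update_stick_posteriors(resp, prior, V, G, K)
  resp$tau <- mcoclust:::update_tau(b, stats_list, U, sticks, blocks, V, G, K)
  upd <- mcoclust:::update_eta(b, stats_list, resp$tau, sticks, blocks, V, G, K)
  resp$eta <- upd$eta
  fast <- mcoclust:::compute_elbo(b, stats_list, resp, sticks, blocks, prior,
                                  V, G, K, elik = upd$elik)
  slow <- mcoclust:::compute_elbo(b, stats_list, resp, sticks, blocks, prior,
                                  V, G, K)
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("masked cells are inert: arbitrary values under the mask change nothing", {
  set.seed(55)
  X <- matrix(rnorm(40), 10, 4)
  X[sample(40, 8)] <- NA
  b1 <- mcc_bundle(as.data.frame(X), "gaussian")
  # the mask is the only source of truth: plant junk under the mask
  b2 <- b1
  b2$families$gaussian$X[b2$families$gaussian$mask == 0] <- 1e6
  r1 <- fit_small(b1, V = 2, G = 2, K = 2, seed = 77, sweeps = 20)
  r2 <- fit_small(b2, V = 2, G = 2, K = 2, seed = 77, sweeps = 20)
  expect_equal(r1$trace, r2$trace, tolerance = 1e-12)
  expect_equal(r1$resp, r2$resp, tolerance = 1e-12)
})

test_that("one sweep is equivariant under object and feature permutations", {
  b <- tiny_gaussian_bundle(n = 6, d = 4, seed = 12)
  V <- 2; G <- 2; K <- 2
  prior <- mcc_prior()
  resp <- random_resp(b, V, G, K, seed = 8)
  run_sweep <- function(bundle, resp) {
    stats_list <- lapply(bundle$families, function(s)
      mcoclust:::family_stats(s$X, s$mask, s$family, s$n_levels))
    U <- list(gaussian = mcoclust:::compute_U(stats_list$gaussian, resp$eta, V))
    blocks <- mcoclust:::update_blocks(bundle, stats_list, U, resp, prior, V, G, K)
    sticks <- mcoclust:::update_stick_posteriors(resp, prior, V, G, K)
    tau <- mcoclust:::update_tau(bundle, stats_list, U, sticks, blocks, V, G, K)
    eta <- mcoclust:::update_eta(bundle, stats_list, tau, sticks, blocks, V, G, K)$eta
    list(tau = tau$gaussian, eta = eta)
  }
  base <- run_sweep(b, resp)
  po <- sample(6); pf <- sample(4)
  bp <- b
  bp$families$gaussian$X <- b$families$gaussian$X[po, pf]
  bp$families$gaussian$mask <- b$families$gaussian$mask[po, pf]
  respp <- resp
  respp$tau$gaussian <- resp$tau$gaussian[pf, , drop = FALSE]
  respp$eta <- resp$eta[po, , , drop = FALSE]
  perm <- run_sweep(bp, respp)
  expect_equal(perm$tau, base$tau[pf, ], tolerance = 1e-10)
  expect_equal(perm$eta, base$eta[po, , , drop = FALSE], tolerance = 1e-10)
})

test_that("presets configure the model's special cases", {
  expect_equal(mcc_preset("cocluster", 10, 5, 10)$V, 1L)
  expect_equal(mcc_preset("restricted", 10, 5, 10)$G, 1L)
  expect_equal(mcc_preset("mixture", 10, 5, 10, d_total = 7),
               list(V = 1L, G = 7L, K = 10))
  expect_error(mcc_preset("bogus", 10, 5, 10), "unknown mode")
  set.seed(20)
  X <- matrix(rnorm(80, rep(c(0, 3), each = 10)), 20, 4)
  fr <- mcoclust(X, "gaussian", V = 3, G = 2, K = 3, mode = "restricted",
                 n_restarts = 2, max_iter = 30, seed = 5)
  for (y in fr$feature_assignment) expect_true(all(y$cluster == 1))
  # restricted mode must also handle mixed types (G = 1 degenerate dims)
  set.seed(77)
  dfm <- data.frame(g = rnorm(12), p = rpois(12, 2),
                    c = sample(c("a", "b"), 12, TRUE))
  fm <- mcoclust(dfm, c("gaussian", "poisson", "categorical"),
                 V = 2, G = 3, K = 2, mode = "restricted",
                 n_restarts = 1, max_iter = 10, seed = 8)
  for (y in fm$feature_assignment) expect_true(all(y$cluster == 1))
  # cocluster preset equals an explicit single-view truncation on the same seed
  fc1 <- mcoclust(X, "gaussian", V = 5, G = 2, K = 3, mode = "cocluster",
                  n_restarts = 2, max_iter = 30, seed = 6)
  fc2 <- mcoclust(X, "gaussian", V = 1, G = 2, K = 3, n_restarts = 2,
                  max_iter = 30, seed = 6)
  expect_equal(fc1$elbo, fc2$elbo, tolerance = 1e-12)
  expect_identical(fc1$object_assignment, fc2$object_assignment)
})

test_that("a converged fit is a fixed point of the sweep", {
  set.seed(14)
  X <- matrix(rnorm(60, rep(c(0, 4), each = 15)), 30, 2)
  b <- mcc_bundle(as.data.frame(X), "gaussian", standardize = FALSE)
  res <- fit_small(b, V = 2, G = 2, K = 2, seed = 3, sweeps = 100)
  stats_list <- lapply(b$families, function(s)
    mcoclust:::family_stats(s$X, s$mask, s$family, s$n_levels))
  # one more sweep from the converged state
  resp <- res$resp
  U <- list(gaussian = mcoclust:::compute_U(stats_list$gaussian, resp$eta, 2))
  blocks <- mcoclust:::update_blocks(b, stats_list, U, resp, mcc_prior(), 2, 2, 2)
  sticks <- mcoclust:::update_stick_posteriors(resp, mcc_prior(), 2, 2, 2)
  resp$tau <- mcoclust:::update_tau(b, stats_list, U, sticks, blocks, 2, 2, 2)
  upd <- mcoclust:::update_eta(b, stats_list, resp$tau, sticks, blocks, 2, 2, 2)
  resp$eta <- upd$eta
  new_elbo <- mcoclust:::compute_elbo(b, stats_list, resp, sticks, blocks,
                                      mcc_prior(), 2, 2, 2, elik = upd$elik)
  expect_lt(abs(new_elbo - res$elbo) / abs(res$elbo), 1e-8)
})

test_that("per-sweep work scales linearly in objects and features", {
  run_ops <- function(n, d) {
    set.seed(1)
    X <- matrix(rnorm(n * d), n, d)
    X[1, 1] <- NA  # dense mask: every statistic touches all n * d cells
    b <- mcc_bundle(as.data.frame(X), "gaussian", standardize = FALSE)
    stats_list <- lapply(b$families, function(s)
      mcoclust:::family_stats(s$X, s$mask, s$family, s$n_levels))
    mcoclust:::mcc_reset_ops()
    set.seed(2)
    mcoclust:::run_restart(b, stats_list, mcc_prior(), 3, 2, 3, 2, 1e-12)
    mcoclust:::mcc_get_ops()
  }
  base <- run_ops(20, 10)
  expect_equal(run_ops(40, 10) / base, 2, tolerance = 0.01)
  expect_equal(run_ops(20, 30) / base, 3, tolerance = 0.01)
  expect_equal(run_ops(40, 30) / base, 6, tolerance = 0.01)
})

test_that("the best restart maximizes the final ELBO and seeds reproduce fits", {
  set.seed(3)
  X <- matrix(rnorm(40, rep(c(0, 2), 10)), 20, 2)
  f1 <- mcoclust(X, "gaussian", V = 2, G = 2, K = 2, n_restarts = 4,
                 max_iter = 25, seed = 42)
  finals <- sapply(f1$elbo_trace, function(tr) tr[length(tr)])
  expect_equal(f1$best_restart, which.max(finals))
  expect_equal(f1$elbo, max(finals))
  f2 <- mcoclust(X, "gaussian", V = 2, G = 2, K = 2, n_restarts = 4,
                 max_iter = 25, seed = 42)
  expect_identical(f1$object_assignment, f2$object_assignment)
  expect_equal(f1$elbo, f2$elbo)
  expect_error(mcoclust(X, "gaussian", n_restarts = 0), "at least 1")
})
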