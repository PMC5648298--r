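# Independent, deliberately slow scalar oracles used to check the vectorized
# implementation: direct evaluation of the variational updates, a
# pair-enumeration ARI, classical conjugate updates on replicated data, and
# the exact truncated-model log marginal of a tiny Gaussian instance.

# ---- tiny fixtures --------------------------------------------------------

tiny_gaussian_bundle <- function(n = 4, d = 2, seed = 1, missing = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * d, mean = rep(c(0, 3), each = n / 2)), n, d)
  if (missing > 0) X[matrix(runif(n * d) < missing, n, d)] <- NA
  mcc_bundle(as.data.frame(X), "gaussian", standardize = FALSE)
}

mixed_bundle <- function(n = 6, seed = 2) {
  set.seed(seed)
  df <- data.frame(
    g1 = rnorm(n), g2 = rnorm(n, 2),
    p1 = rpois(n, 2), p2 = rpois(n, 4),
    c1 = sample(c("a", "b"), n, TRUE), c2 = sample(c("x", "y", "z"), n, TRUE),
    stringsAsFactors = FALSE
  )
  mcc_bundle(df, c("gaussian", "gaussian", "poisson", "poisson",
                   "categorical", "categorical"), standardize = FALSE)
}

random_resp <- function(bundle, V, G, K, seed) {
  set.seed(seed)
  mcoclust:::init_responsibilities(bundle, V, G, K)
}

# ---- scalar expected log-likelihood (re-derived, loop form) ---------------

oracle_eloglik <- function(family, x, post) {
  if (family == "gaussian") {
    0.5 * (digamma(post$a) - log(post$b)) - 0.5 * log(2 * pi) -
      post$a / (2 * post$b) * (x - post$m)^2 - 1 / (2 * post$beta)
  } else if (family == "poisson") {
    x * (digamma(post$a) - log(post$b)) - post$a / post$b - lgamma(x + 1)
  } else {
    digamma(post$alpha[x]) - digamma(sum(post$alpha))
  }
}

# extract one block's posterior from the package's array representation
block_at <- function(blocks_m, family, k, g, v) {
  if (family == "gaussian")
    list(m = blocks_m$m[k, g, v], beta = blocks_m$beta[k, g, v],
         a = blocks_m$a[k, g, v], b = blocks_m$b[k, g, v])
  else if (family == "poisson")
    list(a = blocks_m$a[k, g, v], b = blocks_m$b[k, g, v])
  else
    list(alpha = blocks_m$alpha[k, g, v, ])
}

# ---- scalar (non-vectorized) variational updates --------------------------

# feature-responsibility scores by direct summation over cells and clusters
oracle_update_tau <- function(bundle, eta, sticks, blocks, V, G, K) {
  out <- list()
  for (m in names(bundle$families)) {
    slab <- bundle$families[[m]]
    d <- ncol(slab$X)
    logit <- matrix(NA_real_, d, G * V)
    for (j in seq_len(d)) for (v in seq_len(V)) for (g in seq_len(G)) {
      s <- 0
      for (k in seq_len(K)) for (i in seq_len(bundle$n)) {
        if (slab$mask[i, j] == 1) {
          post <- block_at(blocks[[m]], slab$family, k, g, v)
          s <- s + eta[i, k, v] * oracle_eloglik(slab$family, slab$X[i, j], post)
        }
      }
      gv <- sticks$view
      s <- s + digamma(gv$g1[v]) - digamma(gv$g1[v] + gv$g2[v])
      if (v > 1) for (t in 1:(v - 1))
        s <- s + digamma(gv$g2[t]) - digamma(gv$g1[t] + gv$g2[t])
      gf <- sticks$feat[[m]]
      s <- s + digamma(gf$g1[g, v]) - digamma(gf$g1[g, v] + gf$g2[g, v])
      if (g > 1) for (t in 1:(g - 1))
        s <- s + digamma(gf$g2[t, v]) - digamma(gf$g1[t, v] + gf$g2[t, v])
      logit[j, (v - 1) * G + g] <- s
    }
    p <- exp(logit - apply(logit, 1, max))
    out[[m]] <- p / rowSums(p)
  }
  out
}

oracle_update_eta <- function(bundle, tau, sticks, blocks, V, G, K) {
  n <- bundle$n
  eta <- array(NA_real_, dim = c(n, K, V))
  for (v in seq_len(V)) {
    logit <- matrix(NA_real_, n, K)
    for (i in seq_len(n)) for (k in seq_len(K)) {
      s <- 0
      for (m in names(bundle$families)) {
        slab <- bundle$families[[m]]
        for (g in seq_len(G)) for (j in seq_len(ncol(slab$X))) {
          if (slab$mask[i, j] == 1) {
            post <- block_at(blocks[[m]], slab$family, k, g, v)
            s <- s + tau[[m]][j, (v - 1) * G + g] *
              oracle_eloglik(slab$family, slab$X[i, j], post)
          }
        }
      }
      go <- sticks$obj
      s <- s + digamma(go$g1[k, v]) - digamma(go$g1[k, v] + go$g2[k, v])
      if (k > 1) for (t in 1:(k - 1))
        s <- s + digamma(go$g2[t, v]) - digamma(go$g1[t, v] + go$g2[t, v])
      logit[i, k] <- s
    }
    p <- exp(logit - apply(logit, 1, max))
    eta[, , v] <- p / rowSums(p)
  }
  eta
}

# scalar stick updates by direct summation
oracle_update_sticks <- function(resp, prior, V, G, K) {
  view_mass <- rep(0, V)
  feat <- list()
  for (m in names(resp$tau)) {
    tm <- resp$tau[[m]]
    g1 <- matrix(0, G, V); g2 <- matrix(0, G, V)
    for (v in seq_len(V)) for (g in seq_len(G)) {
      g1[g, v] <- 1 + sum(tm[, (v - 1) * G + g])
      tail <- 0
      if (g < G) for (t in (g + 1):G) tail <- tail + sum(tm[, (v - 1) * G + t])
      g2[g, v] <- prior$alpha2 + tail
      view_mass[v] <- view_mass[v] + sum(tm[, (v - 1) * G + g])
    }
    feat[[m]] <- list(g1 = g1, g2 = g2)
  }
  vg1 <- 1 + view_mass
  vg2 <- sapply(seq_len(V), function(v)
    prior$alpha1 + if (v < V) sum(view_mass[(v + 1):V]) else 0)
  n <- dim(resp$eta)[1]
  og1 <- matrix(0, K, V); og2 <- matrix(0, K, V)
  for (v in seq_len(V)) for (k in seq_len(K)) {
    og1[k, v] <- 1 + sum(resp$eta[, k, v])
    tail <- 0
    if (k < K) for (t in (k + 1):K) tail <- tail + sum(resp$eta[, t, v])
    og2[k, v] <- prior$beta_obj + tail
  }
  list(view = list(g1 = vg1, g2 = vg2), feat = feat,
       obj = list(g1 = og1, g2 = og2))
}

# ---- pair-enumeration adjusted Rand ---------------------------------------

oracle_ari <- function(p1, p2) {
  n <- length(p1)
  a <- b <- c_ <- d_ <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same1 <- p1[i] == p1[j]; same2 <- p2[i] == p2[j]
    if (same1 && same2) a <- a + 1
    else if (same1 && !same2) b <- b + 1
    else if (!same1 && same2) c_ <- c_ + 1
    else d_ <- d_ + 1
  }
  tot <- a + b + c_ + d_
  exp_idx <- (a + b) * (a + c_) / tot
  max_idx <- ((a + b) + (a + c_)) / 2
  if (max_idx == exp_idx) return(ifelse(a == exp_idx, 1, 0))
  (a - exp_idx) / (max_idx - exp_idx)
}

# ---- classical conjugate updates on replicated data -----------------------

classical_normal_gamma <- function(x, prior) {
  N <- length(x); xbar <- mean(x); S <- sum((x - xbar)^2)
  b0 <- prior$gaussian_beta0
  list(m = (b0 * prior$gaussian_m0 + N * xbar) / (b0 + N),
       beta = b0 + N, a = prior$gaussian_a0 + N / 2,
       b = prior$gaussian_b0 + S / 2 +
         b0 * N * (xbar - prior$gaussian_m0)^2 / (2 * (b0 + N)))
}

# ---- exact log marginal of the truncated Gaussian model -------------------

# E[w^a (1-w)^b] under Beta(1, alpha)
beta_moment <- function(a, b, alpha) beta(1 + a, alpha + b) / beta(1, alpha)

# log marginal likelihood of one Gaussian block under the Normal-Gamma prior
ng_log_marginal <- function(x, prior) {
  N <- length(x)
  if (N == 0) return(0)
  post <- classical_normal_gamma(x, prior)
  -N / 2 * log(2 * pi) + 0.5 * (log(prior$gaussian_beta0) - log(post$beta)) +
    lgamma(post$a) - lgamma(prior$gaussian_a0) +
    prior$gaussian_a0 * log(prior$gaussian_b0) - post$a * log(post$b)
}

# Exhaustive enumeration of log p(X) for the truncated stick-breaking model
# on a tiny all-Gaussian instance (V = G = K = 2): sums over every feature
# assignment and every per-view object partition, with stick probabilities
# integrated exactly via Beta moments and block likelihoods via conjugacy.
oracle_log_marginal <- function(X, prior, V = 2, G = 2, K = 2) {
  n <- nrow(X); d <- ncol(X)
  stopifnot(V == 2, G == 2, K == 2)
  y_opts <- expand.grid(rep(list(1:(G * V)), d))   # col index (v-1)*G+g
  z_opts <- expand.grid(rep(list(1:K), n))
  log_terms <- c()
  for (yi in seq_len(nrow(y_opts))) {
    ycol <- as.integer(y_opts[yi, ])
    yv <- (ycol - 1) %/% G + 1; yg <- (ycol - 1) %% G + 1
    cv <- tabulate(yv, V)
    # p(view counts): w1^{c1} (1-w1)^{c2} * w2^{c2}
    py <- beta_moment(cv[1], cv[2], prior$alpha1) *
      beta_moment(cv[2], 0, prior$alpha1)
    for (v in 1:V) {
      cg <- tabulate(yg[yv == v], G)
      py <- py * beta_moment(cg[1], cg[2], prior$alpha2) *
        beta_moment(cg[2], 0, prior$alpha2)
    }
    for (z1 in seq_len(nrow(z_opts))) for (z2 in seq_len(nrow(z_opts))) {
      zmat <- cbind(as.integer(z_opts[z1, ]), as.integer(z_opts[z2, ]))
      pz <- 1
      for (v in 1:V) {
        ck <- tabulate(zmat[, v], K)
        pz <- pz * beta_moment(ck[1], ck[2], prior$beta_obj) *
          beta_moment(ck[2], 0, prior$beta_obj)
      }
      ll <- 0
      for (v in 1:V) for (g in 1:G) for (k in 1:K) {
        cells <- as.vector(X[zmat[, v] == k, yv == v & yg == g, drop = FALSE])
        ll <- ll + ng_log_marginal(cells, prior)
      }
      log_terms <- c(log_terms, log(py) + log(pz) + ll)
    }
  }
  mx <- max(log_terms)
  mx + log(sum(exp(log_terms - mx)))
}

# run the package's sweep pieces to convergence from a fixed init (used for
# fixed-point and bound checks)
fit_small <- function(bundle, V, G, K, seed, sweeps = 60, prior = mcc_prior()) {
  stats_list <- lapply(bundle$families, function(s)
    mcoclust:::family_stats(s$X, s$mask, s$family, s$n_levels))
  set.seed(seed)
  mcoclust:::run_restart(bundle, stats_list, prior, V, G, K, sweeps, 1e-12)
}
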