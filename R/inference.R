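# Truncated stick-breaking variational Bayes EM.
#
# State per restart:
#   tau    — list per family: d^(m) x (G*V) responsibility matrix, column
#            (v-1)*G + g holds the probability that a feature sits in feature
#            cluster g of view v; rows sum to one.
#   eta    — n x K x V array of object responsibilities; eta[i, , v] sums to
#            one for every object i and view v.
#   sticks — Beta posterior parameters for the view, feature-cluster and
#            object-cluster sticks.
#   blocks — conjugate posterior hyperparameters for every
#            (family, object-cluster k, feature-cluster g, view v) block,
#            stored as K x G x V arrays.
#
# A sweep updates blocks -> sticks -> tau -> eta; each step is the exact
# coordinate maximizer of the evidence lower bound, so the bound is
# non-decreasing across sweeps.

tau_cols <- function(v, G) ((v - 1L) * G + 1L):(v * G)

eta_slice <- function(eta, v) matrix(eta[, , v], nrow = dim(eta)[1], ncol = dim(eta)[2])

# Random initialization: responsibility rows drawn from a sharp symmetric
# Dirichlet.  A small concentration gives near-hard random assignments,
# which consistently reach higher ELBO optima than diffuse (Dirichlet(1))
# starts in weak-signal regimes; see the methods vignette.
init_responsibilities <- function(bundle, V, G, K, init_conc = 0.02) {
  draw <- function(nrow_, ncol_) {
    r <- matrix(stats::rgamma(nrow_ * ncol_, shape = init_conc), nrow_, ncol_)
    r <- r + 1e-300  # guard against all-zero rows at tiny concentrations
    r / rowSums(r)
  }
  tau <- lapply(bundle$families, function(s) draw(ncol(s$X), G * V))
  n <- bundle$n
  eta <- array(0, dim = c(n, K, V))
  for (v in seq_len(V)) eta[, , v] <- draw(n, K)
  list(tau = tau, eta = eta)
}

# Beta posterior parameters of all sticks given the responsibilities.
# gamma1 = 1 + mass at the level, gamma2 = concentration + mass beyond it.
update_stick_posteriors <- function(resp, prior, V, G, K) {
  view_mass <- rep(0, V)
  feat <- list()
  for (m in names(resp$tau)) {
    tm <- resp$tau[[m]]
    mass_gv <- matrix(colSums(tm), G, V)  # feature-cluster mass per view
    view_mass <- view_mass + colSums(mass_gv)
    g2 <- prior$alpha2 + apply_tail_sum(mass_gv)
    feat[[m]] <- list(g1 = 1 + mass_gv, g2 = g2)
  }
  vg2 <- prior$alpha1 + rev(cumsum(rev(view_mass)))[-1]
  view <- list(g1 = 1 + view_mass, g2 = c(vg2, prior$alpha1))

  n <- dim(resp$eta)[1]
  obj_mass <- matrix(0, K, V)
  for (v in seq_len(V)) obj_mass[, v] <- colSums(eta_slice(resp$eta, v))
  obj <- list(g1 = 1 + obj_mass, g2 = prior$beta_obj + apply_tail_sum(obj_mass))
  list(view = view, feat = feat, obj = obj)
}

# column-wise cumulative sums without apply()
col_cumsum <- function(m) {
  cs <- matrix(cumsum(m), nrow(m), ncol(m))
  if (ncol(m) > 1)
    cs <- cs - rep(c(0, cs[nrow(m), -ncol(m)]), each = nrow(m))
  cs
}

# column-wise "mass strictly beyond row r" for a levels x groups matrix
apply_tail_sum <- function(mass) {
  rep(colSums(mass), each = nrow(mass)) - col_cumsum(mass)
}

# E[log pi] contributions of truncated stick-breaking weights:
# psi(g1) - psi(g1+g2) at the level plus the cumulated psi(g2) - psi(g1+g2)
# of all earlier sticks.
stick_elog <- function(g1, g2) {
  tot <- digamma_safe(g1 + g2)
  own <- digamma_safe(g1) - tot
  carry <- digamma_safe(g2) - tot
  if (is.matrix(g1)) own + col_cumsum(carry) - carry
  else own + cumsum(carry) - carry
}

# Responsibility-weighted sufficient statistics U^{(p)} = t(S_p) %*% eta,
# flattened over views into one d x (K*V) product per statistic; shared
# between the block update and the feature-responsibility update of the same
# sweep (both condition on the same eta).  A statistic flagged as constant 1
# (the mask of a fully observed slab) reduces to a rank-one product.
compute_U <- function(stats, eta, V) {
  n <- dim(eta)[1]
  K <- dim(eta)[2]
  eflat <- matrix(eta, n, K * V)
  lapply(stats, function(S) {
    if (isTRUE(attr(S, "all_ones"))) {
      mcc_count_ops(n * K * V + ncol(S))
      matrix(colSums(eflat), ncol(S), K * V, byrow = TRUE)
    } else {
      mcc_count_ops(length(S))
      crossprod(S, eflat)
    }
  })
}

u_cols <- function(v, K) ((v - 1L) * K + 1L):(v * K)

# Linear indices of the (object-cluster, feature-cluster) block diagonal in a
# (K*V) x (G*V) matrix, ordered to match as.vector of a K x G x V array.
# Embedding the per-view coefficient matrices in this block-diagonal layout
# lets a whole sweep's data terms collapse into one matrix product per
# statistic instead of one per view.
blockdiag_index <- function(K, G, V) {
  v <- rep(seq_len(V), each = K * G)
  g <- rep(rep(seq_len(G), each = K), V)
  k <- rep(seq_len(K), G * V)
  row <- (v - 1L) * K + k
  col <- (v - 1L) * G + g
  (col - 1L) * (K * V) + row
}

# embed a K x G x V coefficient array block-diagonally
embed_coefs <- function(coefs, idx, K, G, V) {
  lapply(coefs, function(cf) {
    Cbig <- matrix(0, K * V, G * V)
    Cbig[idx] <- cf
    Cbig
  })
}

# Block posteriors for every family from U and tau.  The responsibility-
# weighted statistic sums of all (v, g, k) blocks sit on the block diagonal
# of crossprod(U, tau).
update_blocks <- function(bundle, stats_list, U_list, resp, prior, V, G, K,
                          idx = blockdiag_index(K, G, V)) {
  blocks <- list()
  for (m in names(bundle$families)) {
    slab <- bundle$families[[m]]
    tau_m <- resp$tau[[m]]
    ss <- lapply(U_list[[m]], function(U) {
      if (V <= 15L) {
        # one dense product; the block sums sit on its block diagonal
        array(crossprod(U, tau_m)[idx], dim = c(K, G, V))
      } else {
        # at deep truncations the dense product wastes a V-fold factor
        out <- array(0, dim = c(K, G, V))
        for (v in seq_len(V))
          out[, , v] <- crossprod(U[, u_cols(v, K), drop = FALSE],
                                  tau_m[, tau_cols(v, G), drop = FALSE])
        out
      }
    })
    blocks[[m]] <- blocks_from_ss(slab$family, ss, prior, slab$n_levels)
  }
  blocks
}

# Feature-responsibility update: for every feature j the log-score of the
# (g, v) pair is the eta-weighted expected log-likelihood of its observed
# cells plus the view and feature-cluster stick terms; normalized over all
# (g, v) pairs by log-sum-exp.
update_tau <- function(bundle, stats_list, U_list, sticks, blocks, V, G, K,
                       coefs_all = NULL, idx = blockdiag_index(K, G, V),
                       stick_terms = NULL) {
  ev_term <- stick_terms$ev %||% stick_elog(sticks$view$g1, sticks$view$g2)
  tau <- list()
  for (m in names(bundle$families)) {
    slab <- bundle$families[[m]]
    coefs <- coefs_all[[m]] %||% family_coefs(slab$family, blocks[[m]])
    Cbig <- embed_coefs(coefs, idx, K, G, V)
    eg_term <- stick_terms$eg[[m]] %||%
      stick_elog(sticks$feat[[m]]$g1, sticks$feat[[m]]$g2)  # G x V
    d <- ncol(slab$X)
    logit <- matrix(0, d, G * V)
    for (p in seq_along(Cbig)) logit <- logit + U_list[[m]][[p]] %*% Cbig[[p]]
    # stick terms: view term per view plus feature-cluster term per (g, v)
    prior_term <- as.vector(eg_term) + rep(ev_term, each = G)
    logit <- sweep(logit, 2, prior_term, "+")
    if (any(rowSums(is.finite(logit)) == 0))
      stop("feature responsibility update produced a degenerate (all -Inf) score row")
    tau[[m]] <- normalize_log_rows(logit)
  }
  tau
}

# Object-responsibility update: per view v and object i, the log-score of
# object cluster k pools the tau-weighted expected log-likelihood over all
# families plus the object-cluster stick terms; normalized over k.  Also
# returns the expected data log-likelihood sum(eta * data_term) of the
# updated state, which the sweep reuses as the ELBO's likelihood term.
update_eta <- function(bundle, stats_list, tau, sticks, blocks, V, G, K,
                       coefs_all = NULL, idx = blockdiag_index(K, G, V),
                       stick_terms = NULL) {
  n <- bundle$n
  ek_term <- stick_terms$ek %||% stick_elog(sticks$obj$g1, sticks$obj$g2)  # K x V
  if (is.null(coefs_all)) {
    coefs_all <- lapply(names(bundle$families), function(m)
      family_coefs(bundle$families[[m]]$family, blocks[[m]]))
    names(coefs_all) <- names(bundle$families)
  }
  # data term for every (k, v) at once: one product per statistic
  dt <- matrix(0, n, K * V)
  for (m in names(bundle$families)) {
    Cbig <- embed_coefs(coefs_all[[m]], idx, K, G, V)
    for (p in seq_along(stats_list[[m]])) {
      S <- stats_list[[m]][[p]]
      Tp <- if (isTRUE(attr(S, "all_ones"))) {
        mcc_count_ops(ncol(tau[[m]]) * n + length(tau[[m]]))
        matrix(colSums(tau[[m]]), n, ncol(tau[[m]]), byrow = TRUE)
      } else {
        mcc_count_ops(length(S))
        S %*% tau[[m]]
      }
      dt <- dt + tcrossprod(Tp, Cbig[[p]])
    }
  }
  # normalize over object clusters within each view
  eflat <- matrix(0, n, K * V)
  for (v in seq_len(V)) {
    cols <- u_cols(v, K)
    logit <- dt[, cols, drop = FALSE] +
      matrix(ek_term[, v], n, K, byrow = TRUE)
    eflat[, cols] <- normalize_log_rows(logit)
  }
  list(eta = array(eflat, dim = c(n, K, V)), elik = sum(eflat * dt))
}

# Evidence lower bound of the current variational state.  Closed form:
# expected complete-data log-likelihood over observed cells, minus the KL of
# every Beta stick, multinomial responsibility, and conjugate block posterior
# against its prior.
compute_elbo <- function(bundle, stats_list, resp, sticks, blocks, prior, V, G, K,
                         elik = NULL, stick_terms = NULL) {
  if (is.null(elik)) {
    elik <- 0
    for (m in names(bundle$families)) {
      slab <- bundle$families[[m]]
      coefs <- family_coefs(slab$family, blocks[[m]])
      for (v in seq_len(V)) {
        ev <- eta_slice(resp$eta, v)
        tv <- resp$tau[[m]][, tau_cols(v, G), drop = FALSE]
        for (p in seq_along(coefs)) {
          S <- stats_list[[m]][[p]]
          mcc_count_ops(length(S))
          ssp <- crossprod(ev, S) %*% tv
          elik <- elik + sum(matrix(coefs[[p]][, , v], K, G) * ssp)
        }
      }
    }
  }

  kl_sticks <- sum(kl_beta(sticks$view$g1, sticks$view$g2, 1, prior$alpha1))
  for (m in names(sticks$feat))
    kl_sticks <- kl_sticks + sum(kl_beta(sticks$feat[[m]]$g1, sticks$feat[[m]]$g2, 1, prior$alpha2))
  kl_sticks <- kl_sticks + sum(kl_beta(sticks$obj$g1, sticks$obj$g2, 1, prior$beta_obj))

  ev_term <- stick_terms$ev %||% stick_elog(sticks$view$g1, sticks$view$g2)
  y_term <- 0
  for (m in names(resp$tau)) {
    eg_term <- stick_terms$eg[[m]] %||%
      stick_elog(sticks$feat[[m]]$g1, sticks$feat[[m]]$g2)
    elogpi <- as.vector(eg_term) + rep(ev_term, each = G)  # order (g within v)
    tm <- resp$tau[[m]]
    y_term <- y_term + sum(tm %*% elogpi) - sum(xlogx(tm))
  }
  ek_term <- stick_terms$ek %||% stick_elog(sticks$obj$g1, sticks$obj$g2)
  z_term <- 0
  for (v in seq_len(V)) {
    ev <- eta_slice(resp$eta, v)
    z_term <- z_term + sum(ev %*% ek_term[, v]) - sum(xlogx(ev))
  }

  kl_blocks <- 0
  for (m in names(blocks))
    kl_blocks <- kl_blocks + family_block_kl(bundle$families[[m]]$family, blocks[[m]], prior)

  elbo <- elik - kl_sticks + y_term + z_term - kl_blocks
  if (!is.finite(elbo)) {
    parts <- c(likelihood = elik, stick_kl = kl_sticks, feature_assignment = y_term,
               object_assignment = z_term, block_kl = kl_blocks)
    bad <- names(parts)[!is.finite(parts)]
    stop("non-finite ELBO; offending component(s): ", paste(bad, collapse = ", "))
  }
  elbo
}

# One restart: random init followed by coordinate-ascent sweeps to
# convergence of the relative ELBO change.
run_restart <- function(bundle, stats_list, prior, V, G, K, max_iter, tol,
                        init_conc = 0.02) {
  resp <- init_responsibilities(bundle, V, G, K, init_conc)
  trace <- numeric(0)
  last <- -Inf
  sticks <- NULL; blocks <- NULL
  idx <- blockdiag_index(K, G, V)
  for (it in seq_len(max_iter)) {
    U <- lapply(names(bundle$families), function(m) NULL)
    names(U) <- names(bundle$families)
    for (m in names(bundle$families))
      U[[m]] <- compute_U(stats_list[[m]], resp$eta, V)
    blocks <- update_blocks(bundle, stats_list, U, resp, prior, V, G, K, idx)
    coefs_all <- lapply(names(bundle$families), function(m)
      family_coefs(bundle$families[[m]]$family, blocks[[m]]))
    names(coefs_all) <- names(bundle$families)
    sticks <- update_stick_posteriors(resp, prior, V, G, K)
    stick_terms <- list(
      ev = stick_elog(sticks$view$g1, sticks$view$g2),
      eg = lapply(sticks$feat, function(f) stick_elog(f$g1, f$g2)),
      ek = stick_elog(sticks$obj$g1, sticks$obj$g2))
    resp$tau <- update_tau(bundle, stats_list, U, sticks, blocks, V, G, K,
                           coefs_all, idx, stick_terms)
    upd <- update_eta(bundle, stats_list, resp$tau, sticks, blocks, V, G, K,
                      coefs_all, idx, stick_terms)
    resp$eta <- upd$eta
    elbo <- compute_elbo(bundle, stats_list, resp, sticks, blocks, prior, V, G, K,
                         elik = upd$elik, stick_terms = stick_terms)
    trace <- c(trace, elbo)
    if (it > 1 && abs(elbo - last) / (abs(last) + 1e-12) < tol) break
    last <- elbo
  }
  list(resp = resp, sticks = sticks, blocks = blocks, trace = trace,
       elbo = trace[length(trace)], iterations = length(trace))
}

# MAP extraction with ties broken toward the lowest index.
map_from_resp <- function(resp, families, V, G, K) {
  map_Y <- list()
  for (m in names(resp$tau)) {
    col <- max.col(resp$tau[[m]], ties.method = "first")
    map_Y[[m]] <- data.frame(
      feature = seq_len(nrow(resp$tau[[m]])),
      view = (col - 1L) %/% G + 1L,
      cluster = (col - 1L) %% G + 1L
    )
  }
  n <- dim(resp$eta)[1]
  map_Z <- matrix(0L, n, V)
  for (v in seq_len(V)) map_Z[, v] <- max.col(eta_slice(resp$eta, v), ties.method = "first")
  list(Y = map_Y, Z = map_Z)
}
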