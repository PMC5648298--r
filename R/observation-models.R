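# Conjugate univariate block models (Gaussian, Poisson, categorical).
#
# Each (view, feature-cluster, object-cluster) block fits one univariate
# distribution to its cells, weighted by the product of feature and object
# responsibilities and by the observed-entry mask.  The vectorized fitting
# path works on per-family "sufficient-statistic" matrices (masked cells
# zeroed) so that a whole family's block updates and expected log-likelihood
# terms reduce to a handful of matrix products.

#' Per-cell responsibility weights for one cluster block
#'
#' The weight of cell (i, j) in a block is the product of the feature's
#' responsibility for the (feature-cluster, view) pair, the object's
#' responsibility for the object cluster within that view, and the
#' observed-entry indicator; masked cells therefore contribute nothing to any
#' posterior update.
#'
#' @param tau_col Feature responsibilities (length = number of columns of the
#'   data slab), entries in `[0, 1]`.
#' @param eta_col Object responsibilities (length = number of rows), entries
#'   in `[0, 1]`.
#' @param mask Binary observed-entry matrix with dimensions rows x columns.
#' @return A matrix of weights in `[0, 1]`, same shape as \code{mask}.
#' @keywords internal
block_weight <- function(tau_col, eta_col, mask) {
  if (!is.matrix(mask) || nrow(mask) != length(eta_col) || ncol(mask) != length(tau_col))
    stop(sprintf("block weight shape mismatch: mask is %d x %d but eta has %d rows, tau %d columns",
                 nrow(mask), ncol(mask), length(eta_col), length(tau_col)))
  outer(eta_col, tau_col) * mask
}

check_block_inputs <- function(x, weights) {
  if (any(weights < 0)) stop("block update received negative weights")
  obs <- weights > 0
  if (any(!is.finite(x[obs]))) stop("block update received non-finite observed values")
  invisible(obs)
}

#' Weighted Normal-Gamma conjugate update for a Gaussian block
#'
#' Fractional-weight generalization of the classical Normal-Gamma update:
#' with \eqn{N = \sum w}, \eqn{\bar x = \sum w x / N} and
#' \eqn{S = \sum w (x - \bar x)^2}, the posterior is
#' \eqn{m = (\beta_0 m_0 + N \bar x)/(\beta_0 + N)}, \eqn{\beta = \beta_0 + N},
#' \eqn{a = a_0 + N/2},
#' \eqn{b = b_0 + S/2 + \beta_0 N (\bar x - m_0)^2 / (2(\beta_0 + N))}.
#' Zero total weight returns the prior unchanged.
#'
#' @param x Numeric data (masked cells may hold arbitrary values; they must
#'   carry zero weight).
#' @param weights Nonnegative weights, same shape as \code{x}.
#' @param prior An \code{\link{mcc_prior}}.
#' @return A list with entries \code{m}, \code{beta}, \code{a}, \code{b}.
#' @keywords internal
update_gaussian_block <- function(x, weights, prior) {
  check_block_inputs(x, weights)
  N <- sum(weights)
  if (N <= 0) {
    return(list(m = prior$gaussian_m0, beta = prior$gaussian_beta0,
                a = prior$gaussian_a0, b = prior$gaussian_b0))
  }
  xw <- ifelse(weights > 0, x, 0)
  xbar <- sum(weights * xw) / N
  S <- sum(weights * (xw - xbar)^2)
  b0 <- prior$gaussian_beta0
  list(
    m = (b0 * prior$gaussian_m0 + N * xbar) / (b0 + N),
    beta = b0 + N,
    a = prior$gaussian_a0 + N / 2,
    b = prior$gaussian_b0 + S / 2 + b0 * N * (xbar - prior$gaussian_m0)^2 / (2 * (b0 + N))
  )
}

#' Weighted Gamma-Poisson conjugate update for a Poisson block
#'
#' Shape gains the weighted count sum, rate the total weight:
#' \eqn{a = a_0 + \sum w x}, \eqn{b = b_0 + \sum w}.
#'
#' @inheritParams update_gaussian_block
#' @return A list with entries \code{a}, \code{b}.
#' @keywords internal
update_poisson_block <- function(x, weights, prior) {
  obs <- check_block_inputs(x, weights)
  xo <- x[obs]
  if (any(xo < 0) || any(xo != round(xo)))
    stop("Poisson block requires nonnegative integer observed counts")
  xw <- ifelse(weights > 0, x, 0)
  list(a = prior$poisson_a0 + sum(weights * xw),
       b = prior$poisson_b0 + sum(weights))
}

#' Weighted Dirichlet update for a categorical block
#'
#' Each Dirichlet count gains the total weight of the cells observed at that
#' level: \eqn{\alpha_l = \alpha_0 + \sum_{x = l} w}.  The level set is fixed
#' from the full dataset, not per block.
#'
#' @inheritParams update_gaussian_block
#' @param n_levels Number of levels of the column's frozen level set.
#' @return A list with entry \code{alpha} (length \code{n_levels}).
#' @keywords internal
update_categorical_block <- function(x, weights, prior, n_levels) {
  obs <- check_block_inputs(x, weights)
  xo <- x[obs]
  if (any(xo < 1 | xo > n_levels | xo != round(xo)))
    stop("categorical level outside the declared support (1..", n_levels, ")")
  alpha <- rep(prior$dirichlet_alpha0, n_levels)
  for (l in seq_len(n_levels)) alpha[l] <- alpha[l] + sum(weights[obs & x == l])
  list(alpha = alpha)
}

#' Expected log-likelihood of one observed cell under a block posterior
#'
#' Computes \eqn{E_{q(\theta)}[\log p(x \mid \theta)]} for a single observed
#' value under the variational posterior of its block.  Gaussian:
#' \eqn{\tfrac12(\psi(a) - \log b) - \tfrac12\log 2\pi - \tfrac{a}{2b}(x-m)^2
#' - \tfrac{1}{2\beta}}.  Poisson: \eqn{x(\psi(a) - \log b) - a/b - \log x!}.
#' Categorical level \eqn{l}: \eqn{\psi(\alpha_l) - \psi(\sum_l \alpha_l)}.
#' Missing cells must be masked upstream and are never passed here.
#'
#' @param family One of \code{"gaussian"}, \code{"poisson"}, \code{"categorical"}.
#' @param x A single observed value (a level index for categorical).
#' @param post Block posterior as returned by the update functions above.
#' @return A scalar.
#' @keywords internal
expected_loglik <- function(family, x, post) {
  switch(family,
    gaussian = {
      if (post$a <= 0 || post$b <= 0 || post$beta <= 0)
        stop("invalid Gaussian block posterior (non-positive a, b, or beta)")
      0.5 * (digamma_safe(post$a) - log(post$b)) - 0.5 * log(2 * pi) -
        (post$a / (2 * post$b)) * (x - post$m)^2 - 1 / (2 * post$beta)
    },
    poisson = {
      if (post$a <= 0 || post$b <= 0)
        stop("invalid Poisson block posterior (non-positive a or b)")
      x * (digamma_safe(post$a) - log(post$b)) - post$a / post$b - lgamma(x + 1)
    },
    categorical = {
      if (any(post$alpha <= 0))
        stop("invalid categorical block posterior (non-positive alpha)")
      digamma_safe(post$alpha[x]) - digamma_safe(sum(post$alpha))
    },
    stop("unknown family: ", family)
  )
}

# ---- vectorized machinery -------------------------------------------------

# Per-family sufficient-statistic matrices (n x d each, masked cells zeroed).
# Gaussian: {mask, x, x^2}; Poisson: {mask, x, lgamma(x+1)}; categorical:
# one indicator matrix per level.  Together with the per-block coefficient
# arrays below, every expected log-likelihood is a linear functional of these.
family_stats <- function(X, mask, family, n_levels = NULL) {
  X0 <- X
  X0[mask == 0 | is.na(X0)] <- 0
  out <- switch(family,
    gaussian = list(mask, X0 * mask, X0^2 * mask),
    poisson = list(mask, X0 * mask, lgamma(X0 + 1) * mask),
    categorical = lapply(seq_len(n_levels), function(l) (X0 == l) * mask),
    stop("unknown family: ", family)
  )
  # a fully observed slab's mask statistic supports rank-one products
  if (family != "categorical" && all(mask == 1)) attr(out[[1]], "all_ones") <- TRUE
  out
}

# Coefficient arrays (K x G x V, one per statistic) mapping a block's
# posterior to the linear form of its expected log-likelihood.
family_coefs <- function(family, post) {
  switch(family,
    gaussian = {
      a <- post$a; b <- post$b; m <- post$m; bt <- post$beta
      dg <- digamma_safe(a)
      list(
        0.5 * (dg - log(b)) - 0.5 * log(2 * pi) - a * m^2 / (2 * b) - 1 / (2 * bt),
        a * m / b,
        -a / (2 * b)
      )
    },
    poisson = {
      a <- post$a; b <- post$b
      c0 <- -a / b
      list(c0, digamma_safe(a) - log(b), array(-1, dim = dim(a)))
    },
    categorical = {
      alpha <- post$alpha  # K x G x V x L
      d3 <- dim(alpha)[1:3]
      tot <- digamma_safe(array(rowSums(alpha, dims = 3), dim = d3))
      L <- dim(alpha)[4]
      lapply(seq_len(L), function(l) {
        al <- array(alpha[, , , l, drop = FALSE], dim = d3)
        digamma_safe(al) - tot
      })
    },
    stop("unknown family: ", family)
  )
}

# Vectorized block posterior update for a whole family.  ss is a list of
# K x G x V arrays of responsibility-weighted statistic sums.
blocks_from_ss <- function(family, ss, prior, n_levels = NULL) {
  switch(family,
    gaussian = {
      N <- ss[[1]]; sx <- ss[[2]]; sxx <- ss[[3]]
      xbar <- sx / pmax(N, 1e-300)  # zero-mass blocks have sx = 0, so xbar = 0
      S <- pmax(sxx - N * xbar^2, 0)
      b0 <- prior$gaussian_beta0
      list(
        m = (b0 * prior$gaussian_m0 + N * xbar) / (b0 + N),
        beta = b0 + N,
        a = prior$gaussian_a0 + N / 2,
        b = prior$gaussian_b0 + S / 2 + b0 * N * (xbar - prior$gaussian_m0)^2 / (2 * (b0 + N))
      )
    },
    poisson = list(a = prior$poisson_a0 + ss[[2]], b = prior$poisson_b0 + ss[[1]]),
    categorical = {
      d <- dim(ss[[1]])
      alpha <- array(prior$dirichlet_alpha0, dim = c(d, n_levels))
      for (l in seq_len(n_levels))
        alpha[, , , l] <- prior$dirichlet_alpha0 + c(ss[[l]])
      list(alpha = alpha)
    },
    stop("unknown family: ", family)
  )
}

# ---- KL divergences of the conjugate posteriors ---------------------------

kl_gamma <- function(a, b, a0, b0) {
  (a - a0) * digamma_safe(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
}

kl_normal_gamma <- function(m, beta, a, b, m0, beta0, a0, b0) {
  kl_gamma(a, b, a0, b0) +
    0.5 * (log(beta / beta0) + beta0 / beta + beta0 * (a / b) * (m - m0)^2 - 1)
}

kl_beta <- function(g1, g2, c1, c2) {
  lbeta(c1, c2) - lbeta(g1, g2) +
    (g1 - c1) * digamma_safe(g1) + (g2 - c2) * digamma_safe(g2) +
    (c1 - g1 + c2 - g2) * digamma_safe(g1 + g2)
}

# q = Dir(alpha), p = Dir(alpha0) (symmetric), both length-L
kl_dirichlet <- function(alpha, alpha0) {
  a0 <- rep(alpha0, length(alpha))
  lgamma(sum(alpha)) - sum(lgamma(alpha)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * (digamma_safe(alpha) - digamma_safe(sum(alpha))))
}

# row-vectorized Dirichlet KL: one block per row of alpha (n_blocks x L)
kl_dirichlet_rows <- function(alpha, alpha0) {
  L <- ncol(alpha)
  tot <- rowSums(alpha)
  sum(lgamma(tot)) - sum(lgamma(alpha)) -
    nrow(alpha) * (lgamma(L * alpha0) - L * lgamma(alpha0)) +
    sum((alpha - alpha0) * (digamma_safe(alpha) - digamma_safe(tot)[row(alpha)]))
}

# total block-posterior KL for one family (arrays over K x G x V)
family_block_kl <- function(family, post, prior) {
  switch(family,
    gaussian = sum(kl_normal_gamma(post$m, post$beta, post$a, post$b,
                                   prior$gaussian_m0, prior$gaussian_beta0,
                                   prior$gaussian_a0, prior$gaussian_b0)),
    poisson = sum(kl_gamma(post$a, post$b, prior$poisson_a0, prior$poisson_b0)),
    categorical = kl_dirichlet_rows(matrix(post$alpha, ncol = dim(post$alpha)[4]),
                                    prior$dirichlet_alpha0),
    stop("unknown family: ", family)
  )
}
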