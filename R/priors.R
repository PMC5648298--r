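#' Prior configuration for the multiple co-clustering model
#'
#' Bundles the conjugate observation-model hyperparameters and the
#' stick-breaking concentration parameters.  Gaussian blocks carry a
#' Normal-Gamma prior on (mean, precision); Poisson blocks a Gamma prior on
#' the rate; categorical blocks a symmetric Dirichlet over the column's level
#' set.  The Gaussian defaults assume standardized features (see
#' \code{\link{mcoclust}}'s \code{standardize} argument).
#'
#' @param gaussian_m0 Prior mean of the block mean.
#' @param gaussian_beta0 Prior scale on the mean's precision (dimensionless).
#' @param gaussian_a0,gaussian_b0 Gamma shape/rate prior for the block precision.
#' @param poisson_a0,poisson_b0 Gamma shape/rate prior for the Poisson rate.
#' @param dirichlet_alpha0 Symmetric Dirichlet concentration per category.
#' @param alpha1 Concentration of the view stick-breaking Beta(1, alpha1) prior.
#' @param alpha2 Concentration of the feature-cluster sticks.
#' @param beta_obj Concentration of the object-cluster sticks.
#'
#' @return An object of class \code{mcc_prior} (a named list).
#' @export
#' @examples
#' mcc_prior()
#' mcc_prior(alpha1 = 2, gaussian_b0 = 0.5)
mcc_prior <- function(gaussian_m0 = 0, gaussian_beta0 = 1,
                      gaussian_a0 = 1, gaussian_b0 = 1,
                      poisson_a0 = 1, poisson_b0 = 1,
                      dirichlet_alpha0 = 1,
                      alpha1 = 1, alpha2 = 1, beta_obj = 1) {
  prior <- list(
    gaussian_m0 = gaussian_m0, gaussian_beta0 = gaussian_beta0,
    gaussian_a0 = gaussian_a0, gaussian_b0 = gaussian_b0,
    poisson_a0 = poisson_a0, poisson_b0 = poisson_b0,
    dirichlet_alpha0 = dirichlet_alpha0,
    alpha1 = alpha1, alpha2 = alpha2, beta_obj = beta_obj
  )
  pos <- c("gaussian_beta0", "gaussian_a0", "gaussian_b0", "poisson_a0",
           "poisson_b0", "dirichlet_alpha0", "alpha1", "alpha2", "beta_obj")
  for (nm in pos) {
    v <- prior[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("prior parameter '", nm, "' must be a single strictly positive number")
  }
  if (!is.numeric(prior$gaussian_m0) || !is.finite(prior$gaussian_m0))
    stop("prior parameter 'gaussian_m0' must be finite")
  structure(prior, class = "mcc_prior")
}

#' @export
print.mcc_prior <- function(x, ...) {
  cat("Multiple co-clustering prior configuration\n")
  cat(sprintf("  Gaussian Normal-Gamma: m0=%g, beta0=%g, a0=%g, b0=%g\n",
              x$gaussian_m0, x$gaussian_beta0, x$gaussian_a0, x$gaussian_b0))
  cat(sprintf("  Poisson Gamma: a0=%g, b0=%g\n", x$poisson_a0, x$poisson_b0))
  cat(sprintf("  Categorical Dirichlet: alpha0=%g\n", x$dirichlet_alpha0))
  cat(sprintf("  Stick concentrations: alpha1=%g, alpha2=%g, beta=%g\n",
              x$alpha1, x$alpha2, x$beta_obj))
  invisible(x)
}
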