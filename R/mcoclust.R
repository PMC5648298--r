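#' Fit a multiple co-clustering model to mixed-type data
#'
#' Simultaneously partitions features into views, features within each view
#' into feature clusters, and objects within each view into object clusters,
#' by variational Bayes EM on a truncated stick-breaking nonparametric
#' mixture.  Each (view, feature-cluster, object-cluster) block is fitted
#' with a univariate conjugate model: Gaussian (Normal-Gamma prior), Poisson
#' (Gamma), or categorical (Dirichlet).  Missing entries (\code{NA}) are
#' ignored in all updates under a missing-at-random assumption.
#'
#' The algorithm runs \code{n_restarts} random restarts; each restart sweeps
#' block, stick, feature- and object-responsibility updates until the
#' relative change of the evidence lower bound (ELBO) falls below \code{tol},
#' and the restart with the highest final ELBO is kept.  Reported clusterings
#' are the MAP assignments of the variational multinomials.
#'
#' Truncation levels \code{V}, \code{G}, \code{K} are upper bounds; the
#' stick-breaking prior prunes unused views and clusters, so the effective
#' numbers of views and clusters are inferred from data.  \code{mode} gives
#' the special cases of the model: \code{"cocluster"} forces a single view
#' (classic check-board co-clustering), \code{"restricted"} a single feature
#' cluster per view (restricted multiple clustering), and \code{"mixture"}
#' one view with as many feature clusters as features (an independent-feature
#' mixture model).
#'
#' @param data Data frame or matrix (objects in rows), or an
#'   \code{\link{mcc_bundle}}.
#' @param families Character vector giving each column's family
#'   (\code{"gaussian"}, \code{"poisson"}, \code{"categorical"}); recycled if
#'   length one.  Ignored when \code{data} is already a bundle.
#' @param V,G,K Truncation levels: maximum numbers of views, feature
#'   clusters per view, and object clusters per view.
#' @param mode Model preset; see Details.
#' @param prior An \code{\link{mcc_prior}}.
#' @param n_restarts Number of random restarts.
#' @param max_iter Maximum sweeps per restart.
#' @param tol Relative ELBO-change convergence threshold.
#' @param init_conc Concentration of the symmetric Dirichlet used for random
#'   initialization of responsibility rows; small values give near-hard
#'   random starts.
#' @param standardize Standardize Gaussian columns before fitting.
#' @param seed Integer master seed; each restart derives a child seed from it.
#' @param verbose Print per-restart progress.
#'
#' @return An object of class \code{mcoclust} with components
#'   \code{feature_assignment} (per-family data frame: feature, view,
#'   feature cluster), \code{object_assignment} (n x V matrix of object
#'   clusters per view), \code{elbo}, \code{elbo_trace} (per restart),
#'   \code{best_restart}, \code{effective_views}, \code{n_object_clusters},
#'   the variational state, and the call configuration.
#' @export
#' @examples
#' set.seed(1)
#' x <- cbind(matrix(rnorm(60, rep(c(0, 4), each = 15)), 30),
#'            matrix(rnorm(60, rep(c(3, 0), each = 15)), 30))
#' fit <- mcoclust(x, "gaussian", V = 3, G = 2, K = 4, n_restarts = 3,
#'                 seed = 7)
#' fit
mcoclust <- function(data, families = "gaussian", V = 10, G = 5, K = 10,
                     mode = c("multiple", "cocluster", "restricted", "mixture"),
                     prior = mcc_prior(), n_restarts = 20, max_iter = 500,
                     tol = 1e-6, init_conc = 0.02, standardize = TRUE,
                     seed = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  bundle <- if (inherits(data, "mcc_bundle")) data
            else mcc_bundle(data, families, standardize = standardize)
  if (n_restarts < 1) stop("n_restarts must be at least 1")
  if (tol <= 0) stop("tol must be positive")
  trunc <- mcc_preset(mode, V = V, G = G, K = K, d_total = bundle$d_total)
  V <- trunc$V; G <- trunc$G; K <- trunc$K
  if (V < 1 || G < 1 || K < 1) stop("truncation levels must be at least 1")

  stats_list <- lapply(bundle$families, function(s)
    family_stats(s$X, s$mask, s$family, s$n_levels))

  seed <- seed %||% sample.int(.Machine$integer.max - 1L, 1)
  child_seeds <- derive_restart_seeds(seed, n_restarts)

  best <- NULL; traces <- vector("list", n_restarts)
  for (s in seq_len(n_restarts)) {
    set.seed(child_seeds[s])
    res <- run_restart(bundle, stats_list, prior, V, G, K, max_iter, tol,
                       init_conc)
    traces[[s]] <- res$trace
    if (verbose)
      message(sprintf("restart %d/%d: ELBO %.4f after %d sweeps",
                      s, n_restarts, res$elbo, res$iterations))
    if (is.null(best) || res$elbo > best$elbo) {
      best <- res
      best$restart <- s
    }
  }

  maps <- map_from_resp(best$resp, bundle$families, V, G, K)
  assigned_views <- sort(unique(unlist(lapply(maps$Y, function(y) y$view))))
  n_clust <- vapply(seq_len(V), function(v) length(unique(maps$Z[, v])), 1L)

  structure(list(
    feature_assignment = maps$Y,
    object_assignment = maps$Z,
    elbo = best$elbo,
    elbo_trace = traces,
    best_restart = best$restart,
    iterations = best$iterations,
    effective_views = assigned_views,
    n_object_clusters = n_clust,
    responsibilities = best$resp,
    sticks = best$sticks,
    blocks = best$blocks,
    bundle = bundle,
    config = list(V = V, G = G, K = K, mode = mode, prior = prior,
                  n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                  init_conc = init_conc, standardize = standardize, seed = seed)
  ), class = "mcoclust")
}

#' Truncation preset for the model's special cases
#'
#' @param mode One of \code{"multiple"}, \code{"cocluster"},
#'   \code{"restricted"}, \code{"mixture"}.
#' @param V,G,K Base truncation levels.
#' @param d_total Total feature count (needed by \code{"mixture"}).
#' @return A list with adjusted \code{V}, \code{G}, \code{K}.
#' @export
mcc_preset <- function(mode, V, G, K, d_total = NULL) {
  switch(mode,
    multiple = list(V = V, G = G, K = K),
    cocluster = list(V = 1L, G = G, K = K),
    restricted = list(V = V, G = 1L, K = K),
    mixture = {
      if (is.null(d_total)) stop("mixture preset needs the total feature count")
      list(V = 1L, G = as.integer(d_total), K = K)
    },
    stop("unknown mode: ", mode)
  )
}

#' @export
print.mcoclust <- function(x, ...) {
  cat("Multiple co-clustering fit (variational Bayes)\n")
  cat(sprintf("  %d objects, %d features, mode '%s'\n",
              x$bundle$n, x$bundle$d_total, x$config$mode))
  cat(sprintf("  ELBO %.4f (best of %d restarts, %d sweeps)\n",
              x$elbo, x$config$n_restarts, x$iterations))
  nv <- length(x$effective_views)
  cat(sprintf("  %d effective view%s:\n", nv, if (nv == 1) "" else "s"))
  for (v in x$effective_views) {
    nf <- sum(vapply(x$feature_assignment, function(y) sum(y$view == v), 1L))
    kv <- x$n_object_clusters[v]
    note <- if (kv == 1) " (non-informative)" else ""
    cat(sprintf("    view %d: %d features, %d object cluster%s%s\n",
                v, nf, kv, if (kv == 1) "" else "s", note))
  }
  invisible(x)
}

#' @export
summary.mcoclust <- function(object, ...) {
  views <- object$effective_views
  tab <- do.call(rbind, lapply(names(object$feature_assignment), function(m) {
    y <- object$feature_assignment[[m]]
    data.frame(family = m, feature = object$bundle$families[[m]]$names,
               view = y$view, feature_cluster = y$cluster)
  }))
  out <- list(features = tab,
              objects = object$object_assignment[, views, drop = FALSE],
              effective_views = views,
              n_object_clusters = object$n_object_clusters[views],
              elbo = object$elbo)
  class(out) <- "summary.mcoclust"
  out
}

#' @export
print.summary.mcoclust <- function(x, ...) {
  cat("Feature assignments (view / feature cluster):\n")
  print(utils::head(x$features, 20))
  if (nrow(x$features) > 20) cat("  ... (", nrow(x$features) - 20, " more)\n", sep = "")
  cat("\nEffective views:", paste(x$effective_views, collapse = ", "), "\n")
  cat("Object clusters per effective view:",
      paste(x$n_object_clusters, collapse = ", "), "\n")
  cat(sprintf("ELBO: %.4f\n", x$elbo))
  invisible(x)
}

#' Posterior mean block parameters of a fitted model
#'
#' Returns, for each family and each populated (view, feature-cluster,
#' object-cluster) block, the posterior mean of its parameters: mean and
#' precision for Gaussian blocks, rate for Poisson, level probabilities for
#' categorical.  Gaussian values are on the fitting scale (standardized when
#' the fit standardized columns).
#'
#' @param object A fitted \code{mcoclust} model.
#' @param ... Unused.
#' @return A data frame of blocks and posterior means (one row per block;
#'   family-specific parameter columns are \code{NA} for other families).
#' @export
coef.mcoclust <- function(object, ...) {
  rows <- list()
  for (m in names(object$blocks)) {
    bl <- object$blocks[[m]]
    fam <- object$bundle$families[[m]]$family
    y <- object$feature_assignment[[m]]
    for (v in unique(y$view)) for (g in unique(y$cluster[y$view == v])) {
      for (k in sort(unique(object$object_assignment[, v]))) {
        row <- data.frame(family = m, view = v, feature_cluster = g,
                          object_cluster = k, mean = NA_real_,
                          precision = NA_real_, rate = NA_real_)
        if (fam == "gaussian") {
          row$mean <- bl$m[k, g, v]
          row$precision <- bl$a[k, g, v] / bl$b[k, g, v]
        } else if (fam == "poisson") {
          row$rate <- bl$a[k, g, v] / bl$b[k, g, v]
        } else {
          al <- bl$alpha[k, g, v, ]
          for (l in seq_along(al)) row[[paste0("p_level", l)]] <- al[l] / sum(al)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA_real_
    r[all_names]
  })
  do.call(rbind, rows)
}

#' ELBO trace plot of a fitted multiple co-clustering model
#'
#' Plots the evidence-lower-bound trace of every restart; the best restart is
#' drawn in color.
#'
#' @param x A fitted \code{mcoclust} model.
#' @param ... Passed to \code{matplot}.
#' @export
plot.mcoclust <- function(x, ...) {
  tr <- x$elbo_trace
  len <- max(vapply(tr, length, 1L))
  M <- sapply(tr, function(t) c(t, rep(NA, len - length(t))))
  if (!is.matrix(M)) M <- matrix(M, nrow = len)
  graphics::matplot(M, type = "l", lty = 1, col = "grey70",
                    xlab = "sweep", ylab = "ELBO", ...)
  graphics::lines(tr[[x$best_restart]], col = "firebrick", lwd = 2)
  invisible(x)
}

#' Assign new objects to the fitted object clusters
#'
#' Performs one object-responsibility update for the new rows against the
#' fitted block and stick posteriors (feature assignments are held fixed),
#' and returns the MAP object cluster of each new row in every effective
#' view.
#'
#' @param object A fitted \code{mcoclust} model.
#' @param newdata Data frame or matrix with the same columns as the training
#'   data.
#' @param ... Unused.
#' @return An integer matrix, rows = new objects, columns = effective views.
#' @export
predict.mcoclust <- function(object, newdata, ...) {
  cfg <- object$config
  bundle <- object$bundle
  if (ncol(as.data.frame(newdata)) != bundle$d_total)
    stop("newdata must have ", bundle$d_total, " columns like the training data")
  lev <- list()
  if (!is.null(bundle$families$categorical)) {
    cs <- bundle$families$categorical
    for (jj in seq_along(cs$names)) lev[[cs$names[jj]]] <- cs$levels[[jj]]
  }
  nb <- mcc_bundle(newdata, bundle$family_of_col, standardize = FALSE, levels = lev)
  # apply the training standardization to gaussian columns
  if (!is.null(nb$families$gaussian) && cfg$standardize) {
    tr <- bundle$families$gaussian
    g <- nb$families$gaussian
    g$X <- sweep(sweep(g$X, 2, tr$center), 2, tr$scale, "/") * g$mask
    nb$families$gaussian <- g
  }
  stats_list <- lapply(nb$families, function(s)
    family_stats(s$X, s$mask, s$family, s$n_levels))
  upd <- update_eta(nb, stats_list, object$responsibilities$tau, object$sticks,
                    object$blocks, cfg$V, cfg$G, cfg$K)
  n <- nb$n
  Z <- matrix(0L, n, cfg$V)
  for (v in seq_len(cfg$V)) Z[, v] <- max.col(eta_slice(upd$eta, v), ties.method = "first")
  Z[, object$effective_views, drop = FALSE]
}

#' @export
logLik.mcoclust <- function(object, ...) {
  structure(object$elbo, class = "logLik", df = NA_integer_,
            nobs = object$bundle$n)
}
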