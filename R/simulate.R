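# Synthetic-data generators for the three simulation designs: the
# conventional three-view check-board design with mixed feature types, the
# 20-view Gaussian design, and the two subspace designs.  Each generator
# returns the raw data (before any standardization) together with the
# ground-truth view / feature-cluster / object-cluster labels.

# Block parameter matrices of the conventional design: rows = object
# clusters, columns = feature clusters.
conventional_params <- function() {
  list(
    gaussian = list(matrix(c(0, 1, 4, 3), 2, 2),
                    matrix(c(0, 1, 2, 5, 4, 3), 3, 2),
                    matrix(c(0, 1, 2, 3, 6, 5, 4, 3), 4, 2)),
    poisson = list(matrix(c(1, 2, 2, 1), 2, 2),
                   matrix(c(1, 2, 3, 3, 2, 1), 3, 2),
                   matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 4, 2)),
    categorical = list(matrix(c(0.1, 0.1, 0.9, 0.9), 2, 2),
                       matrix(c(0.1, 0.5, 0.9, 0.9, 0.5, 0.1), 3, 2),
                       matrix(c(0.1, 0.4, 0.6, 0.9, 0.9, 0.6, 0.4, 0.1), 4, 2))
  )
}

#' Conventional three-view check-board synthetic data
#'
#' Generates the conventional simulation design: three views with two, three
#' and four object clusters, two feature clusters per view for each of three
#' feature families (Gaussian with unit standard deviation, Poisson, binary
#' categorical).  Block parameters follow the design's fixed matrices (rows =
#' object clusters, columns = feature clusters), e.g. Gaussian view-1 means
#' (0, 4; 1, 3).  View memberships are evenly assigned to features; feature-
#' and object-cluster memberships are allocated uniformly at random.
#' Optionally a fraction of cells is masked uniformly at random.
#'
#' @param n Number of objects (the study's levels: 20, 50, 100).
#' @param d_per_view Features per view per family (levels: 10, 50, 100).
#' @param missing_rate Proportion of missing entries (levels: 0, 0.1, 0.2).
#' @param seed Optional integer seed.
#' @return A list with \code{data} (data frame, Gaussian then Poisson then
#'   categorical columns), \code{families}, and \code{truth}: per-family
#'   feature view/cluster labels, the n x 3 matrix of true object clusters,
#'   and the generating block parameters.
#' @export
#' @examples
#' sim <- sim_conventional(n = 20, d_per_view = 10, seed = 1)
#' dim(sim$data)
sim_conventional <- function(n, d_per_view = 10, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  pars <- conventional_params()
  n_views <- 3L
  Kv <- c(2L, 3L, 4L)
  d <- d_per_view

  obj_cluster <- sapply(Kv, function(k) sample.int(k, n, replace = TRUE))

  fams <- c("gaussian", "poisson", "categorical")
  data_cols <- list(); fam_col <- character(0)
  truth_view <- list(); truth_fc <- list()
  for (fam in fams) {
    view_of <- rep(seq_len(n_views), each = d)
    fc_of <- integer(0)
    X <- matrix(NA_real_, n, n_views * d)
    for (j in seq_len(n_views * d)) {
      v <- view_of[j]
      g <- sample.int(2L, 1L)
      fc_of <- c(fc_of, g)
      par <- pars[[fam]][[v]][obj_cluster[, v], g]
      X[, j] <- switch(fam,
        gaussian = stats::rnorm(n, mean = par, sd = 1),
        poisson = stats::rpois(n, lambda = par),
        categorical = stats::rbinom(n, 1, prob = par) + 1)
    }
    colnames(X) <- paste0(substr(fam, 1, 1), seq_len(ncol(X)))
    data_cols[[fam]] <- X
    fam_col <- c(fam_col, rep(fam, ncol(X)))
    truth_view[[fam]] <- view_of
    truth_fc[[fam]] <- fc_of
  }
  df <- as.data.frame(do.call(cbind, data_cols))
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * ncol(df)) < missing_rate, n, ncol(df))
    df[mask] <- NA
  }
  df[, fam_col == "categorical"] <- lapply(df[, fam_col == "categorical", drop = FALSE],
                                           function(x) c("no", "yes")[x])
  list(data = df, families = fam_col,
       truth = list(view_of_feature = truth_view,
                    feature_cluster_of_feature = truth_fc,
                    object_cluster = obj_cluster,
                    params = pars, n_views = n_views, Kv = Kv))
}

#' Many-view Gaussian synthetic data (20 true views)
#'
#' Generates a 30 x 2000 Gaussian matrix comprising 20 views of 100 features
#' each.  In views 1-19 the objects split into two clusters of 15 with means
#' 2v-1 and 2v and standard deviation 0.1, with object-cluster membership
#' randomized independently per view; view 20 is pure standard normal noise
#' (a non-informative view).  This design is fitted without standardization.
#'
#' @param seed Optional integer seed.
#' @return A list with \code{data} (30 x 2000 matrix), \code{families}, and
#'   \code{truth} (feature view labels and per-view object clusters).
#' @export
sim_many_views <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 30L; fpv <- 100L; n_views <- 20L
  X <- matrix(NA_real_, n, fpv * n_views)
  obj_cluster <- matrix(1L, n, n_views)
  for (v in seq_len(n_views)) {
    cols <- ((v - 1L) * fpv + 1L):(v * fpv)
    if (v < n_views) {
      ord <- sample.int(n)
      cl <- integer(n); cl[ord[1:15]] <- 1L; cl[ord[16:30]] <- 2L
      mu <- ifelse(cl == 1L, 2 * v - 1, 2 * v)
      X[, cols] <- matrix(stats::rnorm(n * fpv, mean = mu, sd = 0.1), n, fpv)
      obj_cluster[, v] <- cl
    } else {
      X[, cols] <- matrix(stats::rnorm(n * fpv), n, fpv)
    }
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  list(data = X, families = rep("gaussian", ncol(X)),
       truth = list(view_of_feature = list(gaussian = rep(seq_len(n_views), each = fpv)),
                    feature_cluster_of_feature = list(gaussian = rep(1L, ncol(X))),
                    object_cluster = obj_cluster, n_views = n_views))
}

#' Subspace-structured Gaussian synthetic data
#'
#' Generates the 300 x 12 subspace designs with three object clusters of 100
#' and four relevant features per cluster; cluster means are 0, 2 and 3 with
#' standard deviation \code{1/sqrt(precision)}, and background cells are
#' standard normal.  Type 1 places each cluster's relevant features in a
#' disjoint block of four columns (features 1-4, 5-8, 9-12); Type 2 puts all
#' three clusters in the same four columns, leaving eight background
#' features.
#'
#' @param type 1 (disjoint subspaces) or 2 (shared subspace).
#' @param precision Precision of the relevant cells (study levels: 1, 4,
#'   100, 10000).
#' @param seed Optional integer seed.
#' @return A list with \code{data} (300 x 12 matrix), \code{families}, and
#'   \code{truth} (object clusters of size 100 each, relevant-feature map).
#' @export
sim_subspace <- function(type = 1, precision = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!type %in% c(1, 2)) stop("type must be 1 or 2")
  n <- 300L; d <- 12L
  means <- c(0, 2, 3)
  sd_rel <- 1 / sqrt(precision)
  cl <- rep(1:3, each = 100L)
  X <- matrix(stats::rnorm(n * d), n, d)
  relevant <- matrix(FALSE, 3, d)
  if (type == 1) {
    for (c_ in 1:3) {
      cols <- ((c_ - 1L) * 4L + 1L):(c_ * 4L)
      relevant[c_, cols] <- TRUE
      X[cl == c_, cols] <- stats::rnorm(sum(cl == c_) * 4L, mean = means[c_], sd = sd_rel)
    }
  } else {
    cols <- 1:4
    relevant[, cols] <- TRUE
    for (c_ in 1:3)
      X[cl == c_, cols] <- stats::rnorm(sum(cl == c_) * 4L, mean = means[c_], sd = sd_rel)
  }
  colnames(X) <- paste0("f", seq_len(d))
  list(data = X, families = rep("gaussian", d),
       truth = list(object_cluster = matrix(cl, ncol = 1),
                    relevant_features = relevant, means = means,
                    precision = precision))
}

#' Mask entries of a dataset uniformly at random
#'
#' Each cell is masked independently with the given probability (missing at
#' random by construction; masking does not depend on cell values).  Values
#' are replaced by \code{NA}; the pre-masking data are returned alongside so
#' that masked-cell invariance can be audited.
#'
#' @param data Data frame or matrix.
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A list with \code{data} (masked copy), \code{mask} (binary matrix,
#'   0 = missing), and \code{original}.
#' @export
inject_missing <- function(data, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  df <- as.data.frame(data)
  mask <- matrix(1, nrow(df), ncol(df))
  if (rate > 0) {
    drop <- matrix(stats::runif(nrow(df) * ncol(df)) < rate, nrow(df), ncol(df))
    mask[drop] <- 0
    for (j in seq_len(ncol(df))) df[drop[, j], j] <- NA
  }
  list(data = df, mask = mask, original = as.data.frame(data))
}
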