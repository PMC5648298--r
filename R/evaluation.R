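# Partition-comparison metrics and the view-matching evaluation protocols.

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected pair-counting agreement computed from the
#' contingency table: \eqn{(\mathrm{Index} - E[\mathrm{Index}]) /
#' (\mathrm{Max} - E[\mathrm{Max}])} over object pairs.  1 means identical
#' partitions (up to label renaming), values near 0 mean chance-level
#' agreement.
#'
#' @param p1,p2 Label vectors of equal length (any atomic type).
#' @return A scalar in `[-1, 1]`.
#' @export
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c("b", "b", "a", "a"))  # 1
adjusted_rand <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("partitions must have the same number of elements (",
         length(p1), " vs ", length(p2), ")")
  if (!length(p1)) stop("partitions must contain at least one element")
  tab <- table(p1, p2)
  n <- length(p1)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- a * b / tot
  mx <- (a + b) / 2
  if (mx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (mx - expected)
}

# object partitions of the fit's effective views (>= 1 MAP-assigned feature)
effective_object_partitions <- function(fit) {
  views <- fit$effective_views
  if (!length(views)) stop("fit has zero effective views")
  lapply(views, function(v) fit$object_assignment[, v])
}

#' View-matched mean object-cluster ARI
#'
#' The view-matching protocol for object clusterings: because view numbering
#' is arbitrary, each true view's object partition is compared against every
#' yielded view's partition, the maximum ARI is kept, and the maxima are
#' averaged over true views.  A single yielded view may match several true
#' views (no assignment constraint).  For a single-view (co-clustering) fit
#' this reduces to averaging the ARI of the one yielded solution against each
#' true view.
#'
#' @param truth_partitions True object partitions: a matrix with one column
#'   per true view, or a list of label vectors.
#' @param fit A fitted \code{\link{mcoclust}} model, or a matrix/list of
#'   yielded object partitions.
#' @return Mean over true views of the best-matching ARI.
#' @export
view_matched_ari <- function(truth_partitions, fit) {
  truths <- if (is.matrix(truth_partitions))
    lapply(seq_len(ncol(truth_partitions)), function(v) truth_partitions[, v])
  else truth_partitions
  yields <- if (inherits(fit, "mcoclust")) effective_object_partitions(fit)
            else if (is.matrix(fit)) lapply(seq_len(ncol(fit)), function(v) fit[, v])
            else fit
  if (!length(yields)) stop("fit has zero views")
  best <- vapply(truths, function(tr)
    max(vapply(yields, function(y) adjusted_rand(tr, y), 1.0)), 1.0)
  mean(best)
}

#' ARI of view-membership recovery
#'
#' Adjusted Rand index between the true feature-to-view partition and the
#' fit's MAP feature-to-view partition, pooled over all families.
#'
#' @param truth_views True view label per feature: a list per family (in the
#'   fit's family order) or a single pooled vector.
#' @param fit A fitted \code{\link{mcoclust}} model or a pooled vector of
#'   yielded view labels.
#' @return A scalar ARI.
#' @export
view_membership_ari <- function(truth_views, fit) {
  tv <- if (is.list(truth_views)) unlist(truth_views, use.names = FALSE) else truth_views
  fv <- if (inherits(fit, "mcoclust"))
    unlist(lapply(fit$feature_assignment, function(y) y$view), use.names = FALSE)
  else fit
  adjusted_rand(tv, fv)
}

#' Number of perfectly recovered views
#'
#' Counts the true views whose feature set is exactly the feature set of some
#' yielded view (set equality, the strictest reading of error-free
#' recovery).  Two true views merged into one yielded view count as zero.
#'
#' @inheritParams view_membership_ari
#' @return An integer count.
#' @export
perfect_view_count <- function(truth_views, fit) {
  tv <- if (is.list(truth_views)) unlist(truth_views, use.names = FALSE) else truth_views
  fv <- if (inherits(fit, "mcoclust"))
    unlist(lapply(fit$feature_assignment, function(y) y$view), use.names = FALSE)
  else fit
  if (length(tv) != length(fv)) stop("feature counts differ")
  count <- 0L
  for (v in unique(tv)) {
    members <- which(tv == v)
    yv <- unique(fv[members])
    if (length(yv) == 1L && identical(which(fv == yv), members)) count <- count + 1L
  }
  count
}

#' Permutation test for an adjusted Rand index
#'
#' Permutes the second partition's labels uniformly at random and reports the
#' add-one-corrected tail probability
#' \eqn{p = (1 + \#\{ARI_{perm} \ge ARI_{obs}\}) / (1 + n_{perm})}.
#'
#' @param p1,p2 Label vectors of equal length.
#' @param n_perm Number of permutations (at least 1).
#' @param seed Optional integer seed.
#' @return A list with \code{ari} (observed), \code{p_value} and
#'   \code{n_perm}.
#' @export
ari_permutation_test <- function(p1, p2, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1) stop("n_perm must be at least 1")
  obs <- adjusted_rand(p1, p2)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (adjusted_rand(p1, sample(p2)) >= obs) hits <- hits + 1L
  }
  list(ari = obs, p_value = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}
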