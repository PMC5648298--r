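#' Assemble a mixed-type dataset bundle
#'
#' Splits a data frame (or matrix) column-wise into per-family slabs
#' (Gaussian, Poisson, categorical), builds the observed-entry mask from
#' \code{NA} cells, freezes categorical level sets from the full column, and
#' optionally standardizes Gaussian columns using observed-cell mean and
#' standard deviation.
#'
#' @param data A data frame or numeric matrix, one row per object.
#' @param families Character vector, one of \code{"gaussian"},
#'   \code{"poisson"}, \code{"categorical"} per column.  A single value is
#'   recycled to all columns.
#' @param standardize Logical; standardize Gaussian columns (default
#'   \code{TRUE}).  Ignored for other families.
#' @param levels Optional named list of explicit level vectors for
#'   categorical columns; levels otherwise frozen in first-appearance order.
#' @return An object of class \code{mcc_bundle}: a list with the object count
#'   \code{n}, total feature count \code{d_total}, and one slab per family
#'   present, each holding the coded data matrix, the binary observed mask,
#'   column names, and categorical level sets.
#' @export
#' @examples
#' d <- data.frame(g = rnorm(10), p = rpois(10, 2), c = sample(c("a", "b"), 10, TRUE))
#' b <- mcc_bundle(d, c("gaussian", "poisson", "categorical"))
#' b$n
mcc_bundle <- function(data, families, standardize = TRUE, levels = NULL) {
  if (is.matrix(data)) data <- as.data.frame(data)
  if (!is.data.frame(data) || nrow(data) < 1L) stop("data must be a non-empty data frame or matrix")
  d_total <- ncol(data)
  if (length(families) == 1L) families <- rep(families, d_total)
  if (length(families) != d_total)
    stop("families must name one family per column (", d_total, " columns, ",
         length(families), " families)")
  families <- match.arg(families, c("gaussian", "poisson", "categorical"),
                        several.ok = TRUE)
  cn <- colnames(data) %||% paste0("V", seq_len(d_total))
  n <- nrow(data)

  slabs <- list()
  for (fam in c("gaussian", "poisson", "categorical")) {
    idx <- which(families == fam)
    if (!length(idx)) next
    X <- matrix(NA_real_, n, length(idx))
    lev <- vector("list", length(idx))
    for (jj in seq_along(idx)) {
      col <- data[[idx[jj]]]
      nm <- cn[idx[jj]]
      if (fam == "categorical") {
        col_chr <- as.character(col)
        lv <- levels[[nm]] %||% unique(col_chr[!is.na(col_chr)])
        if (!length(lv)) stop("all-missing column: ", nm)
        code <- match(col_chr, lv)
        if (any(!is.na(col_chr) & is.na(code)))
          stop("unseen categorical level in column ", nm)
        X[, jj] <- code
        lev[[jj]] <- lv
      } else {
        if (!is.numeric(col)) {
          suppressWarnings(num <- as.numeric(as.character(col)))
          if (any(!is.na(col) & is.na(num)))
            stop("non-numeric value in ", fam, " column ", nm)
          col <- num
        }
        obs <- col[!is.na(col)]
        if (!length(obs)) stop("all-missing column: ", nm)
        if (fam == "poisson" && (any(obs < 0) || any(obs != round(obs))))
          stop("Poisson column ", nm, " must hold nonnegative integer counts")
        if (fam == "gaussian" && any(!is.finite(obs)))
          stop("non-finite value in gaussian column ", nm)
        X[, jj] <- col
      }
    }
    mask <- 1 * !is.na(X)
    center <- rep(0, length(idx)); scale_ <- rep(1, length(idx))
    if (fam == "gaussian" && standardize) {
      for (jj in seq_along(idx)) {
        o <- mask[, jj] == 1
        mu <- mean(X[o, jj]); sd_ <- stats::sd(X[o, jj])
        if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
        X[o, jj] <- (X[o, jj] - mu) / sd_
        center[jj] <- mu; scale_[jj] <- sd_
      }
    }
    X[mask == 0] <- 0
    n_levels <- if (fam == "categorical") max(vapply(lev, length, 1L)) else NULL
    if (fam == "categorical") {
      # pad shorter level sets; levels are per-column but the slab carries the max
      n_levels <- max(vapply(lev, length, 1L))
    }
    slabs[[fam]] <- list(family = fam, X = X, mask = mask, names = cn[idx],
                         cols = idx, levels = lev, n_levels = n_levels,
                         center = center, scale = scale_)
  }
  structure(list(n = n, d_total = d_total, families = slabs,
                 colnames = cn, family_of_col = families),
            class = "mcc_bundle")
}

#' @export
print.mcc_bundle <- function(x, ...) {
  cat(sprintf("Mixed-type dataset bundle: %d objects, %d features\n", x$n, x$d_total))
  for (s in x$families) {
    miss <- 1 - mean(s$mask)
    cat(sprintf("  %-11s %4d features, %.1f%% missing\n", s$family, ncol(s$X), 100 * miss))
  }
  invisible(x)
}
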