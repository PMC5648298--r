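# File formats, the experiment runner, and the plumbing behind the
# command-line wrapper (inst/cli/mcoclust.R).
#
# Data travel as plain CSV/TSV (header row of feature names, one row per
# object, missing cells empty or "NA"); the feature specification and the run
# manifest are JSON; experiment configurations are YAML.

#' Read a dataset and feature specification into a bundle
#'
#' The feature specification is a JSON array of per-column entries
#' \code{{"name": ..., "family": ...}} with optional \code{"standardize"}
#' (Gaussian only, default \code{true}) and \code{"levels"} (categorical).
#' Every data column must be covered exactly once.
#'
#' @param data_path CSV or TSV file (delimiter inferred from the extension).
#' @param spec_path JSON feature-specification file.
#' @return An \code{\link{mcc_bundle}}.
#' @export
read_dataset <- function(data_path, spec_path) {
  sep <- if (grepl("\\.tsv$", data_path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(data_path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  spec <- jsonlite::fromJSON(spec_path, simplifyDataFrame = FALSE)
  nm <- vapply(spec, function(s) s$name, "")
  fam <- vapply(spec, function(s) s$family, "")
  if (!all(fam %in% c("gaussian", "poisson", "categorical")))
    stop("invalid family in feature spec: ",
         paste(setdiff(fam, c("gaussian", "poisson", "categorical")), collapse = ", "))
  missing_cols <- setdiff(colnames(df), nm)
  unknown_cols <- setdiff(nm, colnames(df))
  if (length(unknown_cols)) stop("feature spec names unknown column(s): ",
                                 paste(unknown_cols, collapse = ", "))
  if (length(missing_cols)) stop("data column(s) not covered by the feature spec: ",
                                 paste(missing_cols, collapse = ", "))
  if (anyDuplicated(nm)) stop("feature spec covers a column more than once")
  df <- df[, nm, drop = FALSE]
  std <- vapply(spec, function(s) isTRUE(s$standardize %||% TRUE), TRUE)
  levels <- list()
  for (s in spec) if (!is.null(s$levels)) levels[[s$name]] <- unlist(s$levels)
  # bundle standardization is all-or-nothing per family: standardize the
  # gaussian slab only when every gaussian column asks for it
  gaussian_std <- all(std[fam == "gaussian"])
  mcc_bundle(df, fam, standardize = gaussian_std, levels = levels)
}

#' Write a feature specification file
#'
#' @param families Character vector of families, named by column.
#' @param path Output JSON path.
#' @param standardize Default standardize flag for Gaussian columns.
#' @return The path, invisibly.
#' @export
write_feature_spec <- function(families, path, standardize = TRUE) {
  spec <- lapply(names(families), function(nm) {
    s <- list(name = nm, family = unname(families[[nm]]))
    if (s$family == "gaussian") s$standardize <- standardize
    s
  })
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a fitted model to a directory
#'
#' Writes the feature table (\code{features.csv}: feature, family, view,
#' feature_cluster), the object table (\code{objects.csv}: one column per
#' view), the per-restart ELBO traces (\code{elbo_trace.csv}) and a JSON run
#' manifest (\code{manifest.json}: configuration, seed, effective views,
#' categorical level codings, package version).
#'
#' @param fit A fitted \code{\link{mcoclust}} model.
#' @param out_dir Output directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_fit <- function(fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- do.call(rbind, lapply(names(fit$feature_assignment), function(m) {
    y <- fit$feature_assignment[[m]]
    data.frame(feature = fit$bundle$families[[m]]$names,
               family = m, view = y$view, feature_cluster = y$cluster)
  }))
  utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)

  Z <- as.data.frame(fit$object_assignment)
  colnames(Z) <- paste0("view", seq_len(ncol(Z)))
  Z <- cbind(object = seq_len(nrow(Z)), Z)
  utils::write.csv(Z, file.path(out_dir, "objects.csv"), row.names = FALSE)

  tr <- fit$elbo_trace
  trace_df <- do.call(rbind, lapply(seq_along(tr), function(s)
    data.frame(restart = s, sweep = seq_along(tr[[s]]), elbo = tr[[s]])))
  utils::write.csv(trace_df, file.path(out_dir, "elbo_trace.csv"), row.names = FALSE)

  lev <- list()
  if (!is.null(fit$bundle$families$categorical)) {
    cs <- fit$bundle$families$categorical
    lev <- stats::setNames(cs$levels, cs$names)
  }
  manifest <- list(
    package = "mcoclust",
    version = as.character(utils::packageVersion("mcoclust")),
    config = fit$config[c("V", "G", "K", "mode", "n_restarts", "max_iter",
                          "tol", "standardize")],
    prior = unclass(fit$config$prior),
    seed = fit$config$seed,
    best_restart = fit$best_restart,
    elbo = fit$elbo,
    effective_views = fit$effective_views,
    n_object_clusters = fit$n_object_clusters,
    categorical_levels = lev
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read back a written fit's assignments
#'
#' @param fit_dir Directory written by \code{\link{write_fit}}.
#' @return A list with \code{features}, \code{objects} (matrix) and
#'   \code{manifest}.
#' @export
read_fit <- function(fit_dir) {
  feats <- utils::read.csv(file.path(fit_dir, "features.csv"),
                           stringsAsFactors = FALSE)
  obj <- utils::read.csv(file.path(fit_dir, "objects.csv"))
  Z <- as.matrix(obj[, -1, drop = FALSE])
  manifest <- jsonlite::fromJSON(file.path(fit_dir, "manifest.json"))
  list(features = feats, objects = Z, manifest = manifest)
}

# ---- experiment runner ----------------------------------------------------

experiment_defaults <- function() {
  list(design = "conventional", replicates = 3, seed = 1,
       n = c(20, 50, 100), d_per_view = c(10, 50, 100),
       missing_rate = c(0, 0.1, 0.2),
       type = c(1, 2), precision = 1,
       mode = "multiple", V = 10, G = 5, K = 10,
       n_restarts = 20, max_iter = 100, tol = 3e-5)
}

#' Run a simulation-study experiment
#'
#' Loops generate, fit, evaluate over the factor grid of one of the three
#' synthetic designs and returns per-replicate metrics plus factor-level
#' means.  The configuration may be a YAML file path or a named list; any
#' field omitted falls back to the defaults (conventional design, factor
#' levels n in \{20, 50, 100\}, features per view in \{10, 50, 100\}, missing
#' rates \{0, 0.1, 0.2\}, 3 replicates, 20 restarts).  Every dataset and fit
#' seed derives deterministically from the experiment seed, so identical
#' configurations reproduce identical summaries.
#'
#' @param config YAML file path or named list; see Details.
#' @return A list with \code{metrics} (one row per dataset: factor levels,
#'   replicate, object-cluster ARI, view ARI, perfect view count, ELBO) and
#'   \code{means} (factor-level means in the layout of the study's summary
#'   tables).
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(experiment_defaults(), config)
  design <- match.arg(cfg$design, c("conventional", "many_views", "subspace"))

  grid <- switch(design,
    conventional = expand.grid(n = cfg$n, d_per_view = cfg$d_per_view,
                               missing_rate = cfg$missing_rate,
                               rep = seq_len(cfg$replicates)),
    many_views = expand.grid(rep = seq_len(cfg$replicates)),
    subspace = expand.grid(type = cfg$type, precision = cfg$precision,
                           rep = seq_len(cfg$replicates)))

  dataset_seeds <- derive_restart_seeds(cfg$seed, 2L * nrow(grid))
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, , drop = FALSE]
    gen_seed <- dataset_seeds[2L * r - 1L]
    fit_seed <- dataset_seeds[2L * r]
    if (design == "conventional") {
      sim <- sim_conventional(n = g$n, d_per_view = g$d_per_view,
                              missing_rate = g$missing_rate, seed = gen_seed)
      standardize <- TRUE
    } else if (design == "many_views") {
      sim <- sim_many_views(seed = gen_seed)
      standardize <- FALSE
    } else {
      sim <- sim_subspace(type = g$type, precision = g$precision, seed = gen_seed)
      standardize <- TRUE
    }
    # the 20-view design needs truncation above the true view count; bump the
    # default unless the configuration sets V explicitly
    V <- if (design == "many_views" && is.null(config$V)) 25L else cfg$V
    fit <- mcoclust(sim$data, sim$families, V = V, G = cfg$G, K = cfg$K,
                    mode = cfg$mode, n_restarts = cfg$n_restarts,
                    max_iter = cfg$max_iter, tol = cfg$tol,
                    standardize = standardize, seed = fit_seed)
    obj_ari <- view_matched_ari(sim$truth$object_cluster, fit)
    vw_ari <- if (!is.null(sim$truth$view_of_feature))
      view_membership_ari(sim$truth$view_of_feature, fit) else NA_real_
    pvc <- if (!is.null(sim$truth$view_of_feature))
      perfect_view_count(sim$truth$view_of_feature, fit) else NA_integer_
    rows[[r]] <- cbind(g, data.frame(object_ari = obj_ari, view_ari = vw_ari,
                                     perfect_views = pvc, elbo = fit$elbo,
                                     effective_views = length(fit$effective_views)))
  }
  metrics <- do.call(rbind, rows)

  factor_cols <- setdiff(colnames(grid), "rep")
  means <- NULL
  if (length(factor_cols)) {
    means <- do.call(rbind, lapply(factor_cols, function(fc) {
      agg <- stats::aggregate(metrics[, c("object_ari", "view_ari")],
                              by = list(level = metrics[[fc]]), mean)
      cbind(data.frame(factor = fc), agg)
    }))
  } else {
    means <- data.frame(factor = "overall", level = NA,
                        object_ari = mean(metrics$object_ari),
                        view_ari = mean(metrics$view_ari))
  }
  list(metrics = metrics, means = means, config = cfg)
}
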