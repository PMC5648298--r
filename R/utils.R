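# internal helpers shared across the package

.mcc_env <- new.env(parent = emptyenv())
.mcc_env$ops <- 0

# cell-touch operation counter: incremented by the sufficient-statistic
# products so that per-sweep cost can be audited independently of wall-clock
mcc_reset_ops <- function() {
  .mcc_env$ops <- 0
  invisible(NULL)
}

mcc_get_ops <- function() .mcc_env$ops

mcc_count_ops <- function(n) {
  .mcc_env$ops <- .mcc_env$ops + n
  invisible(NULL)
}

# row-wise log-sum-exp normalization; returns probabilities with rows summing
# to one exactly (renormalized after the exp(-700) underflow floor)
normalize_log_rows <- function(logp) {
  mx <- logp[cbind(seq_len(nrow(logp)), max.col(logp, ties.method = "first"))]
  p <- exp(logp - mx)
  p[p < 1e-304] <- 1e-304  # exp(-700) underflow floor
  p / rowSums(p)
}

# digamma with the positivity guard used throughout the variational updates;
# the guard is only materialized when a parameter actually underflows
digamma_safe <- function(x) {
  if (min(x) < 1e-12) x <- pmax(x, 1e-12)
  digamma(x)
}

# x * log(x) with the 0 * log(0) = 0 convention
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

# derive one reproducible child seed per restart from the master seed
derive_restart_seeds <- function(seed, n_restarts) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_restarts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
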