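# mcoclust

Multiple co-clustering of mixed-type data via nonparametric Bayesian
mixtures, fitted by variational Bayes EM.

## The problem

Tabular datasets in biostatistics and epidemiology — symptom scores, event
counts, binary status flags side by side — often contain **several**
clustering structures at once: one group of variables separates the subjects
one way, another group a different way.  A single global clustering blurs
them together.  `mcoclust` partitions the *columns* into **views**, the
columns within each view into **feature clusters**, and the *rows* into
**object clusters separately within every view**, so each view carries its
own complete clustering solution.

Formally, each (view $v$, feature cluster $g$, object cluster $k$) block is
modelled by one univariate conjugate distribution — Gaussian
(Normal–Gamma prior), Poisson (Gamma) or categorical (Dirichlet) — and the
complete-data log-likelihood is

$$\log p(X \mid Y, Z, \Theta) = \sum_{m,v,g,k,j,i}
  Y^{(m)}_{j,v,g} Z_{i,v,k} \log p\!\left(X^{(m)}_{i,j} \mid \theta^{(m)}_{v,g,k}\right),$$

with feature memberships $Y$ and per-view object memberships $Z$ drawn from
truncated stick-breaking (Dirichlet-process) priors, so the numbers of
views and clusters are inferred from data rather than fixed.  Inference is
mean-field variational Bayes with closed-form coordinate updates, random
restarts, and MAP extraction; missing entries are handled by simply
dropping them from every update (missing at random).  Setting the view
truncation to 1 recovers classic co-clustering; one feature cluster per
view recovers restricted multiple clustering.

## A worked example

Two planted views over 100 objects: columns 1–20 cluster the rows one way,
columns 21–40 a different way.

```r
library(mcoclust)

set.seed(2)
cl1 <- rep(1:2, each = 50)          # view 1's true object clusters
cl2 <- rep(1:2, 50)                 # view 2's: a different split
X <- cbind(matrix(rnorm(100 * 20, mean = 4 * (cl1 - 1)), 100, 20),
           matrix(rnorm(100 * 20, mean = 4 * (cl2 - 1)), 100, 20))

fit <- mcoclust(X, families = "gaussian", V = 5, G = 3, K = 5,
                n_restarts = 10, seed = 42)
fit
#> Multiple co-clustering fit (variational Bayes)
#>   100 objects, 40 features, mode 'multiple'
#>   ELBO -2710.1769 (best of 10 restarts, 162 sweeps)
#>   2 effective views:
#>     view 1: 20 features, 2 object clusters
#>     view 3: 20 features, 2 object clusters

# recovery, against the planted structure
view_membership_ari(rep(1:2, each = 20), fit)   # feature-to-view recovery
#> [1] 1
view_matched_ari(cbind(cl1, cl2), fit)          # object clusters, view-matched
#> [1] 1
```

The fit found exactly two populated views out of the truncation of five,
each with the two planted object clusters; both adjusted Rand indices are 1,
i.e. the feature partition and both row partitions are recovered perfectly.
`summary(fit)` lists per-feature assignments, `coef(fit)` the posterior
block parameters, `plot(fit)` the ELBO traces, and `predict(fit, newX)`
assigns held-out rows to the learned clusters in every view.

Mixed types and missing data work the same way: pass a data frame, name
each column's family, and leave gaps as `NA`:

```r
fit <- mcoclust(df, families = c("gaussian", "poisson", "categorical", ...))
```

Synthetic designs, evaluation metrics and a reproducible experiment loop
are exported as `sim_conventional()`, `sim_many_views()`, `sim_subspace()`,
`adjusted_rand()`, `view_matched_ari()`, `view_membership_ari()`,
`perfect_view_count()`, `ari_permutation_test()` and `run_experiment()`.
A thin command-line wrapper with `simulate` / `fit` / `evaluate` /
`experiment` subcommands lives at `inst/cli/mcoclust.R`.

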