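# tracemtl

Multitask learning for drug-sensitivity prediction in cancer cell lines.

Large pharmacological screens (CCLE, CTD2, NCI60, GDSC, ...) measure the
response of hundreds of molecularly characterized cell lines to panels of
drugs, and the standard modeling practice has been to train one regularized
regression per drug — typically an elastic net on gene expression, copy
number and mutation features. Training each drug separately ignores that
related drugs (same target, same mechanism of action) depend on the same
underlying cellular programs. `tracemtl` trains all drug models **jointly**
with trace-norm (nuclear-norm) regularization, which couples the tasks by
pulling their coefficient vectors into a shared low-dimensional subspace,
and is aimed at computational biologists who work with cell-line-by-feature
and cell-line-by-drug response matrices.

## The model

Given a feature matrix **X** ∈ ℝ^(N×P) (N cell lines, P molecular features)
and a response matrix **Y** ∈ ℝ^(N×T) (T drugs, entries possibly missing),
the package fits the coefficient matrix **W** = (w₁ … w_T) ∈ ℝ^(P×T) and
intercepts b ∈ ℝ^T minimizing

    Σ_t Σ_{i ∈ obs(t)} ( y_ti − w_tᵀ x_i − b_t )²  +  λ ‖W‖₊

where ‖W‖₊ is the trace norm (sum of singular values), a convex surrogate
for rank. The problem is solved by ADMM on the split W = Z: the W-update
decomposes into independent per-task ridge-augmented regressions (solved in
closed form from cached SVD factorizations), the Z-update is singular-value
soft-thresholding S_{λ/ρ}, and the dual update is gradient ascent. Paths
over a geometric λ grid are warm-started from the previous solution.

Around the solver, the package provides the pieces of a complete
drug-response study:

* **Baselines** — per-task elastic net (glmnet-parameterized objective,
  11-point α grid, 100-point λ path in [0.01 λmax, λmax]) and a
  feature-free "nearest drug response neighbor" predictor.
* **Evaluation** — inductive (whole cell lines held out) and transductive
  (per-drug entries held out, features always visible) split plans, nested
  5-fold cross-validation, paired one-sided Wilcoxon signed-rank
  comparisons, and a task-number ablation.
* **Label-noise analysis** — a permutation test per drug asking whether
  models trained on true labels beat models trained on permuted labels
  (one-sided rank-sum over replicated 80/20 splits).
* **Interpretation** — Ward clustering of per-drug model vectors, adjusted
  Rand index against mechanism-of-action annotations, and hypergeometric
  gene-set enrichment of each model's top-weighted features (GMT input).
* **Synthetic data** — a generator for low-rank multitask panels with
  mutation-like binary features, mechanism groups and permuted "noisy
  drugs", so the entire pipeline is testable offline.

## Worked example

```r
library(tracemtl)

# synthetic panel: 80 cell lines x 50 features, 20 drugs, rank-2 truth
dat  <- generate_synthetic(synthetic_spec(N = 80, P = 50, T = 20, rank = 2,
                                          noise_sd = 0.5, seed = 1))
plan <- make_split_plan(dat$responses, "transductive", k = 5, seed = 2)

cv_tn <- nested_cv(dat$features, dat$responses, plan, "trace_norm",
                   inner_k = 3, n_lambda = 20, folds = 1)
cv_en <- nested_cv(dat$features, dat$responses, plan, "elastic_net",
                   folds = 1)
compare_paired(cv_tn, cv_en)
#> comparison_report: 18 wins, 2 losses, 0 ties; one-sided signed-rank
#> P = 6.68e-06; mean MSE reduction 42.2%
```

Trace norm wins on 18 of the 20 drugs with a 42% average reduction in
held-out mean squared error relative to per-drug elastic nets — the
transductive multitask advantage on data with shared low-rank structure.
A final model for interpretation is refit on all data at a λ selected by
cross-validation:

```r
fit <- fit_trace_norm_cv(dat$features, dat$responses, k = 3, seed = 3,
                         n_lambda = 20)
fit$model
#> multitask_model: 50 features x 20 tasks, lambda = 40.7485, rank = 14,
#> converged in 51 iterations
labels <- flat_cut(cluster_drug_models(fit$model$W), k = 6)
```

`fit$model$W` is exactly low-rank (it is the thresholded ADMM iterate);
its columns can be clustered, cut into flat groups, compared with
mechanism-of-action annotations via `adjusted_rand()`, and fed to
`top_feature_enrichment()` with a GMT gene-set collection.

A command-line driver with `simulate` / `fit` / `benchmark` / `noise` /
`interpret` subcommands is installed at
`system.file("cli", "tracemtl.R", package = "tracemtl")`.

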