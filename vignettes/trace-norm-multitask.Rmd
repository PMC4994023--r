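---
title: "Trace-norm multitask regression for drug sensitivity: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trace-norm multitask regression for drug sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Drug-response panels pair a feature matrix $X \in \mathbb{R}^{N \times P}$
(gene expression, copy number, binarized mutation status for $N$ cell
lines) with a response matrix $Y \in \mathbb{R}^{N \times T}$ (one
response summary per cell line and drug: activity area on a 0–8 scale,
AUC on 0–16, or $-\log_{10}$ GI50, depending on the screen). $P$ is tens
of thousands, $N$ a few hundred at best, and the per-drug responses are
noisy — the classic setting in which independently trained models overfit
and disagree.

`tracemtl` fits all $T$ drug models jointly:

$$
\min_{W,\,b}\; \sum_{t=1}^{T} \sum_{i \in \mathrm{obs}(t)}
  \left(y_{ti} - w_t^\top x_i - b_t\right)^2 \;+\; \lambda \lVert W \rVert_*
$$

with $W = (w_1 \dots w_T) \in \mathbb{R}^{P \times T}$ and unpenalized
intercepts $b$. The trace norm $\lVert W \rVert_*$ (sum of singular
values) is the convex envelope of rank on the spectral ball: penalizing
it forces the task coefficient vectors to span a low-dimensional subspace
of feature space, which is exactly the structure expected when drugs
share targets or mechanisms of action. Each task sees only its observed
rows $\mathrm{obs}(t)$, so missing responses — including deliberately
held-out ones — never touch the fit.

The key modeling assumptions are (i) a common linear read-out from
features to response across tasks, (ii) approximate low rank of the true
coefficient matrix, and (iii) additive, roughly homoscedastic response
noise. The synthetic generator (below) produces data satisfying these
assumptions exactly; real screens satisfy them at best approximately.

# The ADMM solver

The objective is split as $f(W, b) + \lambda\lVert Z\rVert_*$ subject to
$W = Z$, giving the augmented Lagrangian (dual variable $\Gamma$, penalty
$\rho$)

$$
\mathcal{L}_\rho = f(W, b) + \lambda \lVert Z \rVert_* +
  \operatorname{tr}\!\big(\Gamma^\top (W - Z)\big) +
  \tfrac{\rho}{2}\lVert W - Z\rVert_F^2 .
$$

The intercepts are unpenalized and therefore live only in the first
variable block. Each iteration performs:

1. **W-update.** $\mathcal{L}_\rho$ separates over tasks; each
   $(w_t, b_t)$ minimizes
   $\lVert y_t - X^{(t)} w - b\mathbf{1}\rVert^2 +
   \tfrac{\rho}{2}\lVert w - z_t + \rho^{-1}\gamma_t\rVert^2$, a
   ridge-augmented regression solved in closed form. Because $X^{(t)}$
   never changes within a fit, its centered thin SVD is factorized once
   (`admm_designs()`), after which every iteration costs only
   matrix–vector products: $O(T \cdot P \cdot \min(N, P))$ per sweep.
2. **Z-update.** $Z \leftarrow S_{\lambda/\rho}(W + \rho^{-1}\Gamma)$,
   singular-value soft-thresholding (`svd_shrink()`), the proximal
   operator of the trace norm. This iterate is *exactly* low-rank.
3. **Dual update.** $\Gamma \leftarrow \Gamma + \rho (W - Z)$.

**Stopping.** Joint primal/dual residual criterion:
$\lVert W - Z\rVert_F \le \sqrt{PT}\,\varepsilon_{abs} +
\varepsilon_{rel}\max(\lVert W\rVert_F, \lVert Z\rVert_F)$ and
$\rho\lVert Z^k - Z^{k-1}\rVert_F \le \sqrt{PT}\,\varepsilon_{abs} +
\varepsilon_{rel}\lVert\Gamma\rVert_F$, with defaults
$\varepsilon_{abs} = 10^{-4}$, $\varepsilon_{rel} = 10^{-3}$ and
`max_iter = 2000`. Hitting the cap returns the current iterate with
`converged = FALSE` and a warning rather than an error, so paths degrade
gracefully.

**Penalty parameter.** `rho` defaults to 1 *with adaptive rescaling
enabled*: when the primal residual exceeds ten times the dual residual
the penalty is doubled, and vice versa halved. The design was genuinely
open — a fixed $\rho$ is the textbook presentation — but at the top of
the regularization path the data-fit Hessian dwarfs $\rho = 1$ and fixed-
penalty iterations converge extremely slowly, while the adaptive rule
reaches the same objectives (relative differences around $10^{-6}$ in
our tests) orders of magnitude faster. `adaptive_rho = FALSE` restores
the fixed behavior.

**Warm starts.** `fit_trace_norm_path()` fits a strictly decreasing
$\lambda$ sequence, initializing each fit from the previous full ADMM
state; the first fit starts at zero, which is near-optimal at the top of
the path. The grid is geometric with 50 points in
$[0.01\,\lambda_{\max}, \lambda_{\max}]$ by default, where
$\lambda_{\max}$ is the spectral norm of the matrix whose $t$-th column
is $2 X_c^{(t)\top}(y_t - \bar y_t)$ — by the subgradient condition the
smallest penalty at which $W = 0$ is optimal.

**Standardization.** Features are standardized to zero mean and unit
(population) variance over the union of training rows before fitting,
and coefficients are back-transformed for reporting. The trace norm is
not invariant to per-feature rescaling, and drug panels mix continuous
expression with 0/1 mutation indicators, so unstandardized fits would
implicitly up-weight high-variance blocks. `standardize = FALSE` is
available (and used by the solver's oracle tests, which compare against
references formulated in the original scale).

**Reported coefficients.** The returned `W` is the $Z$ iterate — exactly
low-rank, hence the natural object for clustering and enrichment — with
intercepts recomputed to be optimal for it. `rank` counts singular values
above $10^{-8}\sigma_{\max}$.

# Single-task baselines

The elastic net baseline minimizes the glmnet-parameterized objective
$(1/2N)\sum_i (y_i - w^\top x_i - b)^2 +
\lambda(\alpha\lVert w\rVert_1 + (1-\alpha)/2\,\lVert w\rVert_2^2)$.
Hyperparameters follow the two-stage protocol: $\alpha$ over the 11-point
grid $\{0, 0.1, \dots, 1\}$ by 5-fold cross-validation with $\lambda$
free along the path, then $\lambda$ re-optimized at the chosen $\alpha$
over 100 geometric values in $[0.01\lambda_{\max}, \lambda_{\max}]$ with
$\lambda_{\max} = \max_l |x_l^\top(y - \bar y)| / (N\alpha)$. Ties in
cross-validated error break toward the larger (more regularized)
$\lambda$. One subtlety is handled inside `fit_elastic_net()`: glmnet
standardizes the response internally, which silently rescales the
quadratic penalty term by $1/\mathrm{sd}(y)$ while leaving the $\ell_1$
term intact, so the requested $(\alpha, \lambda)$ are reparameterized to
make the returned coefficients minimize the objective exactly as written;
the $\alpha = 0$ case then agrees with the closed-form ridge solution.

The nearest-drug baseline predicts a held-out response of drug $d$ on
cell $c$ from the training responses alone: among drugs observed on $c$,
pick the one with the highest Pearson correlation to $d$ (computed on
jointly observed training cells, minimum overlap 3 — both the
correlation type and the floor are our choices), and evaluate the
univariate regression of $d$ on that neighbor. Ties break toward the
lowest drug index; cells with no admissible neighbor fall back to the
training mean and are flagged. It deliberately never consults the feature
matrix: it quantifies how much of the multitask advantage could be
explained by response-profile similarity alone.

# Cross-validation geometry

Two holdout geometries are distinct in the multitask setting:

* **Inductive** — the same cell lines are held out across all tasks;
  models are scored on fully unseen samples.
* **Transductive** — each task independently holds out a fraction of its
  observed entries; every feature vector is visible during training, and
  prediction amounts to completing missing entries of the response
  matrix. This mirrors the clinical scenario where a patient's molecular
  profile is known but their response to a given drug is not.

Per-task holdouts in transductive plans are drawn uniformly and
independently across tasks (nothing in the setting requires
coordination), and unstratified. Nested cross-validation selects
hyperparameters by an inner split of the *outer-training entries only*,
preserving the outer geometry; a leakage guard errors if any outer test
entry survives in a training mask. Row order after `align_matrices()` is
sorted by cell-line id so that fold draws are reproducible regardless of
input order, and plans serialize to JSON so both learners score identical
test sets — a requirement for the paired one-sided Wilcoxon signed-rank
comparison (`compare_paired()`, exact distribution for at most 25
untied informative tasks, normal approximation with continuity correction
otherwise; with no informative pairs the p-value is reported as 1).

The task-number ablation (`task_group_ablation()`) partitions tasks at
random into groups of a requested size, runs the transductive nested CV
per group, and records each task's error exactly once per group size —
isolating how much of the multitask advantage depends on having many
tasks to share across.

# Label-noise analysis

`noise_test()` asks, per drug, whether an elastic net trained on the true
labels predicts held-out responses better than one trained on permuted
labels: 200 replicates on real labels and 1000 on permuted labels by
default (permuted errors have higher variance), each replicate drawing a
fresh 80/20 split, compared by a one-sided Wilcoxon rank-sum test at a
nominal 0.01 threshold. Two readings of "repeated with replacement" are
possible — independent redraws of the split across replicates, or
bootstrap resampling of rows within a replicate; we implement the former,
and the two are statistically similar. To keep 1200 model fits per drug
affordable, $\alpha$ is selected once on the full data and each replicate
selects only $\lambda$, by a short 20-point path under 3-fold
cross-validation on its training split; replicate counts are arguments,
and the test suite runs reduced counts. `noise_summary()` aggregates pass
fractions, a threshold-sweep curve, and the Pearson correlation between
each drug's response IQR (dynamic range) and $-\log_{10} p$ — informative
drugs tend to be the ones with room to vary.

# Interpretation

Per-drug model vectors (columns of $W$) are clustered with Ward's
minimum-variance criterion on Euclidean distances. We implement the
classic "ward" dialect — `hclust(method = "ward.D")` on *squared*
Euclidean distances — and record the dialect in the output metadata,
since R's historical `"ward"` differs from `ward.D2`. Agreement with
mechanism-of-action annotations is quantified by the adjusted Rand index
in its contingency-table form (cross-checked against brute-force pair
counting in the tests). Gene-set enrichment takes the top 100 features of
a model column — by absolute weight for dense trace-norm models, or by
positive weight with a fall-back to all positive features for sparse
elastic-net models (both modes are exposed, since "highest weighted" is
ambiguous for signed coefficients) — and applies an upper-tail
hypergeometric test against a user-supplied GMT collection's background.
P-values are reported raw; downstream heat-mapping conventions plot
$-\log_{10} p$, and no ontology graph or conditional testing is involved.

# The synthetic generator

`generate_synthetic()` emulates the structure the method assumes:
continuous standard-normal feature columns plus a configurable fraction
of binary columns at 10% prevalence (mutation-like sparsity); a true
coefficient matrix $U V^\top$ of exact rank $r$, rescaled so the average
per-task signal variance is 1 (making `noise_sd` a noise-to-signal
knob); responses $Y = XW + \mathbf{1}b^\top + \varepsilon$; optionally a
fraction of tasks whose finished response column is permuted (drugs whose
labels carry no information), and optionally mechanism groups whose
task-side factors are shared up to jitter, giving ground truth for
clustering. Defaults (`N = 100, P = 50, T = 20, rank = 2,
noise_sd = 0.5`) are the desk-scale study conditions used throughout the
tests.

What the generator does *not* emulate — and hence what passing tests do
not certify about real screens: the correlation structure within and
between expression/copy-number blocks, heavy-tailed and heteroscedastic
response noise, batch effects, dose-response curve artifacts (responses
are drawn directly, never integrated from viability curves), and feature
spaces four orders of magnitude larger than the fixtures.

# Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run at deliberately small
scale, chosen as the smallest sizes at which the qualitative phenomena
are stable across seeds: solver-oracle comparisons on $40 \times 20$
panels with 6 tasks; the transductive benchmark at
$N = 80, P = 50, T = 20$, rank 2, evaluating one fold of a 5-fold plan;
the task ablation at $T = 32$ with group sizes 32 vs 2; the
mechanism-group study at $T = 24$ in 6 groups of 4 with $P = 100 > N =
60$ (the regime where single-task fits are hardest); and reduced
replicate counts in the noise tests. Degenerate inputs are errors, not
silent results: constant responses (undefined $\lambda_{\max}$ and noise
test), tasks with fewer than 5 observed entries at CV time, empty
cell-line intersections, non-finite inputs to the SVD. Zero-variance
feature columns get unit scale (i.e. are centered but not inflated), and
rank-deficient task designs are handled by truncating the cached SVD at
$10^{-12}\sigma_{\max}$.

# Known limitations

* The solver is dense-matrix, single-machine R; it is comfortable to a
  few thousand features but does not exploit sparsity or parallelize the
  per-task W-updates, and no GPU/stochastic variants are provided.
* $\alpha$ selection for the elastic net inside `nested_cv()` happens per
  outer fold on training entries (avoiding the leakage of a global
  pre-selection), which is the dominant cost of the baseline.
* Inference on the comparison (signed-rank p) treats per-task mean MSEs
  as exchangeable paired observations; tasks sharing cell lines are not
  independent, so p-values should be read as descriptive, as is
  conventional.
* Real-data preprocessing (RMA normalization, MAF filtering,
  probe-to-gene collapsing) is out of scope; the package consumes already
  prepared delimited matrices with the conventions documented in
  `read_feature_matrix()` / `read_response_matrix()`.
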