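---
title: "Fuzzy SVMs for imbalanced, noisy classification: model and methods"
author: "fsvmcip maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy SVMs for imbalanced, noisy classification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsvmcip)
```

## The problem

Medical feature tables are typically imbalanced — a large majority of
healthy/normal samples (labelled +1 here) and a small minority of
diseased/abnormal ones (labelled −1) — and they carry outliers and
label noise.  A plain soft-margin SVM reacts to both pathologies the same
way: the separating hyperplane drifts towards the minority class, and
single mislabelled points can dominate the fit.  `fsvmcip` implements a
fuzzy, cost-asymmetric, locality-regularized SVM (FSVM-CIP) that attacks
the three problems with three coupled mechanisms:

1. **Fuzzy memberships** $\mu_i \in (0, 1]$ scale each sample's
   misclassification cost, so samples far from their own class mean —
   likely outliers — are down-weighted.
2. **Class-specific cost scaling**: the effective cost of slack for class
   $c$ is $\mu_i / (v_c\, m_c)$, where $m_c$ is the class size.  The
   $1/m_c$ factor alone already equalizes the *aggregate* cost budget of
   the two classes; choosing $v_2 < v_1$ tilts the budget further towards
   the minority.
3. **A learned secondary margin offset** $\rho \ge 0$: positives are asked
   to satisfy $w^\top x_i + b \ge 1$ while negatives must satisfy
   $-(w^\top x_j + b) \ge 1 + \rho$.  The objective rewards larger $\rho$
   (through a $-\nu\rho$ term), demanding a larger functional margin of
   the minority class and counteracting hyperplane skew.

A fourth ingredient, the **local within-class preserving scatter matrix**
$S_{lw}$, regularizes $w$ towards directions in which nearby same-class
samples stay nearby: $S_{lw}$ accumulates the outer products of residuals
between each sample and the heat-kernel-weighted average of its $k$
nearest within-class neighbors, and the penalty $\tfrac{\eta}{2} w^\top
S_{lw} w$ is added to the margin objective.

## Primal, dual, and how the package solves them

The linear primal is

$$\min_{w, b, \rho, \xi}\; \tfrac12 w^\top w - \nu\rho
 + \frac{1}{v_1 m_1}\sum_{i \le m_1} \mu_i \xi_i
 + \frac{1}{v_2 m_2}\sum_{j > m_1} \mu_j \xi_j
 + \tfrac{\eta}{2}\, w^\top S_{lw} w,$$

subject to $w^\top x_i + b \ge 1 - \xi_i$ for positives,
$-(w^\top x_j + b) \ge 1 + \rho - \xi_j$ for negatives, $\xi \ge 0$,
$\rho \ge 0$.  Eliminating the primal variables gives a convex QP in the
dual multipliers $\alpha$ with matrix
$H_{ij} = y_i y_j\, x_i^\top (I + \eta S_{lw})^{-1} x_j$, box constraints
$0 \le \alpha_i \le \mu_i/(v_c m_c)$, and class-sum constraints.  With
$\rho$ unconstrained both class sums are pinned at $\nu$; carrying the
$\rho \ge 0$ multiplier through instead yields
$\sum_{i \le m_1}\alpha_i = \sum_{j > m_1}\alpha_j \ge \nu$ with a
$-\mathbf{1}^\top\alpha$ linear term.  The two coincide whenever the
$\rho$-free solution has $\rho \ge 0$.

`solveDual()` solves the fixed-sum QP: an interior-point solve
(`kernlab::ipop`) followed by an active-set polish (null-space method on
the free set, so the equality constraints hold exactly even for
rank-deficient $H$), returning multipliers and KKT residuals; residuals
are at machine precision on the instances the test suite draws.
`fitLinearCip()`/`fitKernelCip()` enforce $\rho \ge 0$ on top of it: the
optimal value $V(\nu')$ of the fixed-sum QP is convex in the common sum
$\nu'$, and the $\rho$-constrained optimum minimizes $V(\nu') - 2\nu'$
over $\nu' \in [\nu,\ \text{bound mass}]$, located by a derivative-free
golden-section search (each evaluation is a full QP solve; the search is
skipped whenever the solution at $\nu$ already has $\rho \ge 0$).  The
realized sum is stored as `effectiveNu` in the model's `kkt` slot.
`enforceRhoNonneg = FALSE` restores the fixed-sum behavior, in which
$\rho$ can come out negative on overlapping data — below $-1$ the
minority margin demand is vacuous and the fit degenerates to an
all-positive classifier, which is why the constraint is on by default.

**Threshold recovery.**  $b^*$ is $1$ minus the mean of $w^\top x$ over
the positive-class support vectors; $\rho^*$ comes from averaging the
per-SV solutions of the negative margin equality, giving $\rho^* =
\overline{w^\top x}_{SV_1} - \overline{w^\top x}_{SV_2} - 2$.  The
averages run over *interior* SVs ($0 < \alpha <$ bound) by default: the
margin equalities these formulas solve presuppose zero slack, which
interior SVs satisfy exactly, while bound SVs may sit inside the margin
and would bias the averages (`svRule = "all"` includes them anyway).
When a class has no interior SV — typical for vertex solutions of the
$\rho \ge 0$ search — the thresholds are instead recovered by a direct
minimization of the convex piecewise-linear primal cost in $(b, \rho)$
at the fitted $w$; the model records which path was used
(`kkt$recovery`).

**Kernel case.**  With a kernel $K$ the scatter enters through the
kernel-side terms $T_c = K_c (I - W_c)^\top (I - W_c) K_c^\top$, the dual
matrix is $M = Y K Q^{-1} K Y$ with $Q = K + \eta(T_1 + T_2)$, and the
representer coefficients are $\beta^* = Q^{-1} K Y \alpha^*$.  $Q$ is
factorized by Cholesky with a deterministic escalating ridge
($10^{-10}\,\mathrm{tr}(Q)/N$ base) because $Q$ is only guaranteed
positive semidefinite; $M$ is symmetrized and its positive
semidefiniteness is checked at run time.  Since $\beta^*$ already absorbs
the label matrix $Y$ once, the decision function and thresholds use
$\sum_j \beta_j K(x, x_j)$ *without* a further label factor; this is the
variant under which the linear-kernel fit at $\eta = 0$ reproduces the
linear fit to $10^{-6}$ (asserted in the test suite), and an
`"asPrinted"` variant with the doubled label factor is kept for
comparison.  The model records the variant used.

## Memberships

Two families, each evaluated from the distance $d_i$ of a sample to its
*own* class mean (the normalizing maximum of the linear family also runs
over the own class):

- linear: $\mu_i = 1 - d_i / (d_{\max} + \delta)$, with $\delta = 10^{-6}$
  by default.  Note the farthest sample of each class always receives
  $\mu \approx \delta/d_{\max}$: it is effectively excluded.  With only
  two samples in a class both are "farthest", so this family degenerates
  for very small classes — prefer the exponential family there.
- exponential: $\mu_i = 2 / (1 + e^{\lambda d_i})$ with
  $\lambda \in [0, 1]$; $\lambda = 0$ gives $\mu \equiv 1$ (no
  down-weighting).  $\lambda$ has no default in the protocol and is
  grid-searched.

In the kernel case distances are evaluated in feature space through the
Gram matrix, $\lVert \phi(x_i) - \bar\phi_C \rVert^2 = K_{ii} -
\tfrac{2}{|C|}\sum_{j \in C} K_{ij} + \tfrac{1}{|C|^2}\sum_{s,t \in C}
K_{st}$, clamping tiny negative radicands and rejecting genuinely
indefinite kernel matrices.  Memberships are computed on the training set
only; test samples are never weighted.

## The locality graph and scatter

`withinClassGraph()` connects each sample to its $k$ nearest *within-class*
neighbors (symmetric OR rule, ties broken by smaller index), weights
edges by the heat kernel $e^{-d^2/t}$, and row-normalizes, so each
connected row sums to one.  The self-referential normalization in the
graph's defining formula is read as: raw heat weights first, then row
normalization — the standard construction.  Isolated nodes (class of one,
or truncated $k$) contribute nothing to the scatter: with no neighborhood
there is nothing to preserve, and the literal alternative would inject a
spurious $x_i x_i^\top$ term.  $k$ is truncated to class size − 1 with a
warning.  Neither $k$ nor $t$ has a privileged default; the protocol
grids are $k \in \{3, 5, \dots, 15\}$ and $t \in \{0.5, 1, \dots, 4\}$.

## Evaluation protocol

`scoreClassifier()` reports sensitivity, specificity, accuracy and both
G-means; `cvSelect()` runs stratified 5-fold cross-validation over the
protocol grids (`defaultGrid()`: $\nu \in \{1, 5, \dots, 80\}$, $v_1, v_2
\in \{0.001, 0.005, 0.01, 0.05\}$, $\log_2 \eta \in \{-5, \dots, 6\}$,
Gaussian spread $\sigma$ as $\tau^2$ times $2^{-4} \dots 2^4$ where
$\tau^2$ is the mean squared row norm of the training data), selecting by
mean accuracy with a G-mean tie-break; and `repeatedExperiment()` repeats
a stratified fixed-count split ten times and reports each metric as a
percent mean with the spread on the fraction scale (the benchmark-table
convention, e.g. `95.87 ± 0.017`).  The full grid product is
combinatorially large; `cvSelect(budget = )` evaluates a seeded random
subset.  Selection is by mean accuracy because the benchmark tables this
protocol mirrors are accuracy-led; both G-means are computed and reported
but not used for selection.

## The synthetic-data generator

`simulateDataset()` draws two Gaussian clouds (or interleaved
half-circles, for exercising the kernel path) with a configurable
positive:negative count, dimensionality, and mean separation measured in
pooled within-class standard deviations; it then replaces a fraction of
samples with far-field outliers on a shell at 5–8 times the separation
(keeping their labels — they stress the membership down-weighting), and
flips a fraction of labels.  Counts of outliers and flips are exact
(`round(rate × N)`) and the pre-flip truth is retained in `meta`.
`benchmarkProtocols()` returns five specs mirroring the training shapes
of the standard medical benchmark suite — $(m_1, m_2, d)$ = (240, 120,
9), (80, 20, 13), (100, 10, 19), (150, 10, 6), (180, 10, 8), imbalance
2:1 up to 18:1 — with default separation 2 and 5% label noise.

What the generator does *not* emulate: real feature distributions
(discreteness, skew, heteroscedastic covariance), correlated features,
and structured missingness.  Green tests on the generator therefore
certify the optimization and protocol machinery, not clinical
performance.

The test suite and the acceptance script deliberately run at small scale:
random QP instances at $N \le 10$ against an independent
projected-gradient solver, reductions and invariants at $N \le 20$, the
imbalance comparison on $N = 160$ with ten seeds, and one kernel fit per
benchmark protocol shape ($N$ up to 360).  These sizes make every
property check exhaustive and exact while keeping any single run of the
suite in minutes.

## Numerical choices and degenerate inputs

- QP backend `kernlab::ipop` (interior point), `sigf = 8`; the active-set
  polish drives KKT residuals to linear-solve precision and is also the
  fallback when `ipop` fails at degenerate vertices (its starting points
  are the interior-point solution and the scaled-bounds feasible point).
- Infeasible $\nu$ ($\nu$ above a class's total box mass
  $\sum \mu_i/(v_c m_c)$) is an error naming the limiting class.
- Support vectors are $\alpha > 10^{-8}\max(u)$ (scale-aware); margin
  errors are samples with slack above $10^{-6}$ at the KKT-consistent
  thresholds.
- Predictions map a decision value of exactly zero to +1 (deterministic,
  favoring the majority/normal class).
- `marginBoundsReport()` audits, per class, the chain
  (membership mass of margin errors) $\le \nu_{\text{eff}}\, v_c m_c \le$
  (membership mass of support vectors), reporting all six raw
  quantities; the left bound is flagged vacuous when a class has no
  margin errors.
- Features are used as-is; `standardizeFeatures()` exists but nothing
  calls it implicitly, since the method is defined on raw features.
- Loaders reject missing or non-numeric cells outright (no imputation),
  naming the offending row and column.

## A worked fit

```{r example}
ds <- simulateDataset(simSpec(nPos = 150, nNeg = 10, dim = 6,
                              separation = 2, labelNoiseRate = 0.05,
                              seed = 42))
describeDataSet(ds)

ctl <- cipControl(nu = 10, v1 = 0.01, v2 = 0.005, eta = 2, k = 5, t = 2,
                  family = "exponential", lambda = 0.5)
fit <- fitKernelCip(ds, ctl)
fit
marginBoundsReport(fit)

test <- simulateDataset(simSpec(nPos = 150, nNeg = 10, dim = 6,
                                separation = 2, seed = 43))
unlist(scoreClassifier(classLabels(test),
                       predict(fit, features(test)))[1:5])
```

## Known limitations

- The $\rho \ge 0$ search multiplies the QP cost by the bracketing
  evaluations (a dozen or so solves); for repeated CV over large grids
  this is the dominant cost.
- No precomputed-kernel input path and no kernel caching; the intended
  regime is hundreds of samples, not tens of thousands.
- The linear membership family degenerates for classes of two samples
  (both get the floor value); the loader cannot repair mislabelled
  classes, and hepatitis-style missing values must be resolved upstream.
- With extreme cost asymmetry (aggregate minority budget an order of
  magnitude above the majority's) the optimum is the all-negative
  classifier; that is the correct solution of the stated objective, not a
  solver failure — `marginBoundsReport()` and the recorded
  `kkt$recovery` make such fits easy to recognize.
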