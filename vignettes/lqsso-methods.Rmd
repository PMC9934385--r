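---
title: "Quantile-weighted L1 shrinkage: model, algorithm and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-weighted L1 shrinkage: model, algorithm and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqsso)
```

## The estimator

For a linear model $y = X\beta + \varepsilon$ with centered response and
standardized predictors ($\sum_i x_{ij} = 0$, $\sum_i x_{ij}^2/n = 1$), the
least quantile shrinkage and selection operator (lqsso) solves

$$\hat\beta = \arg\min_\beta \sum_{i=1}^n \Big(y_i - \sum_j \beta_j
x_{ij}\Big)^2 + \lambda \sum_{j=1}^p w_j^q\,|\beta_j|, \qquad
w_j = \begin{cases} \tau & \hat\beta_{j,\mathrm{init}} > 0 \\
1-\tau & \hat\beta_{j,\mathrm{init}} \le 0,\end{cases}$$

where $\hat\beta_{\mathrm{init}}$ is an ordinary-least-squares fit when
$p < n$ and a ridge fit otherwise, and $\tau \in [0,1]$ is a quantile
level.  The weights are the quantile-regression check function
$\rho_\tau(u) = [\tau - I(u \le 0)]u$ evaluated at the sign of the initial
estimate: coefficients whose initial estimate is positive are charged
$\tau$ per unit, the rest $1-\tau$.  Unlike the adaptive lasso, whose
weights $1/|\hat\beta_{j,\mathrm{init}}|^\gamma$ can explode when an
initial estimate is small, lqsso weights always lie between $\min(\tau,
1-\tau)$ and $\max(\tau, 1-\tau)$, and they use the *sign* information the
adaptive lasso discards.  At $\tau = 0.5$ all weights are $1/2$ and the
fit is exactly the lasso at $\lambda/2$ — a property the test suite
asserts to $10^{-8}$.

Two representational choices deserve note:

* **Convex form.**  The penalty is sometimes written in a signed form
  $[\tau - I(\hat\beta_{\mathrm{init}} < 0)]\beta_j$ that can be negative
  when $\mathrm{sign}(\beta_j) \ne
  \mathrm{sign}(\hat\beta_{j,\mathrm{init}})$ and makes the objective
  unbounded.  This package implements the nonnegative weighted-absolute
  form $w_j|\beta_j|$ throughout, which is convex and bounded below; the
  two coincide whenever the fitted sign agrees with the initial sign.
* **Zero initial estimates** fall in the "$\le 0$" branch and receive
  weight $1-\tau$, exactly as the indicator is written.

## Algorithm and numerics

The weighted problem is reduced to a plain lasso by column rescaling
($x_j^* = x_j / w_j^q$, solve, divide the solution by $w_j^q$), and the
lasso is solved by cyclic coordinate descent with exact soft-thresholding
updates, warm starts along descending $\lambda$, sequential strong-rule
screening, and a full Karush–Kuhn–Tucker pass that re-admits any screened
coordinate violating optimality — so a converged solution satisfies the
optimality conditions of the *full* problem.  `kkt_check()` exposes the
same conditions as a user-facing certificate.

Numerical choices:

* **Objective scale.**  All solver functions take $\lambda$ on the raw
  objective scale ($\mathrm{RSS} + \lambda\,\mathrm{penalty}$).
  Per-observation scales used by path solvers correspond through
  $\lambda_{\mathrm{obj}} = 2n\lambda_{\mathrm{obs}}$
  (`lambda_objective()`).  Tuning grids are interpreted on the
  per-observation scale: the benchmark grids $\{0.1, \ldots, 2\}$ only
  produce penalization of the order the benchmark tables display when
  read that way — on the raw objective scale they would be effectively
  unpenalized at $n = 80$ — and this is also the scale a practitioner
  passes to standard path solvers.
* **Convergence** is declared when the largest per-sweep coefficient
  change, measured on the standardized-column scale
  ($|\Delta\beta_j|\sqrt{x_j^\top x_j/n}$, invariant under the column
  rescaling above), drops below `tol` ($10^{-8}$ for single fits,
  $10^5$ sweeps maximum).  Non-convergence is flagged on the fit, never
  silent.
* **Weight clamping.**  At $\tau \in \{0, 1\}$ one sign group would get
  weight zero, breaking the rescaling; weights are clamped below at
  $\varepsilon_w = 10^{-8}$, making those coordinates effectively
  unpenalized.  With $p \ge n$ such cells are degenerate
  (near-interpolating) subproblems on which coordinate descent is slow;
  cross-validation solves therefore run with a looser tolerance
  ($10^{-7}$) and a 1000-sweep cap.  Held-out error only needs ranking
  precision, and the degenerate cells lose the comparison by a wide
  margin, so the selection is unaffected; the chosen cell is refit at the
  tight single-fit settings.
* **Tie-breaking.**  Coordinates are swept in fixed index order.  Equal
  cross-validation errors resolve toward the smallest $\lambda$, then the
  $\tau$ closest to $0.5$ (the least-asymmetric penalty) or the smallest
  $\gamma$.
* **Degenerate requests.**  OLS initials with $p \ge n$ are refused with
  a pointer to `ridge_init()` rather than pseudo-inverted; `ridge_init()`
  selects its own penalty by closed-form leave-one-out cross-validation
  on an SVD over a log-spaced grid, which is deterministic and costs one
  decomposition.

## Tuning

`cv_tune()` performs K-fold cross-validation jointly over $(\tau,
\lambda)$ for lqsso and $(\gamma, \lambda)$ for the adaptive lasso, with
default grids $\lambda, \gamma \in \{0.1, 0.2, \ldots, 2\}$ and $\tau \in
\{0, 0.01, \ldots, 1\}$.  Initial estimates are recomputed on every
training fold, so no held-out information leaks into the weights.  The
benchmark protocol does not state a fold count; the package defaults to
$K = 5$, with `loocv_error()` providing the leave-one-out criterion used
for real-data comparisons.  The selection rule is the arg-min of the mean
held-out error.  (A one-standard-error rule was considered and rejected:
no single selection rule reproduces all published benchmark cells, and
arg-min is the least-assumption default.)

## The synthetic benchmark

`scenario_spec()` / `run_experiment()` generate five data-generating
models: rows are mean-zero Gaussian with $\mathrm{cor}(j,j') =
0.5^{|j-j'|}$, $y = x^\top\beta^* + N(0, \sigma^2)$ with $\sigma \in \{1,
3, 6\}$ and $n \in \{40, 80\}$, evaluated on 1000 fresh test samples per
replicate:

| model | $p$ | truth |
|---|---|---|
| 1 | 8 | 4 nonzero, 4 zeros |
| 2 | 8 | dense |
| 3 | 100 | dense |
| 4 | 100 | 30 nonzero |
| 5 | 1000 | 30 nonzero $\sim N(0.5, 0.5^2)$ |

Metrics per replicate: relative prediction error
$\mathrm{RPE} = E[(\hat y - x^\top\beta^*)^2]/\sigma^2$ (empirical over
the test design; `rpe_analytic()` gives the population quadratic form,
and the two agree within Monte Carlo error), squared-error bias
$\sum_j(\hat\beta_j - \beta^*_j)^2$ (the square root is also emitted), and
the correct/incorrect selection counts $C$ and $I$.  Cell standard errors
use the bootstrap-median scheme: 500 resamples of the per-replicate
values, the standard deviation of the resample medians.

Design choices where the protocol was open:

* **Coefficient mode.**  The benchmark text draws nonzero coefficients
  afresh each replicate (`beta_mode = "random"`, the default).  Its
  stated signal-to-noise ratios (21.25, 2.35, 0.59 for model 1 at
  $\sigma = 1, 3, 6$), however, are exactly
  $\beta^{*\top}\Sigma\beta^*/\sigma^2$ for the classical fixed vector
  $(3, 1.5, 0, 0, 2, 0, 0, 0)$ — and the model-1 table cells (adaptive
  lasso at the oracle error level) are attainable only with such strong
  fixed signals.  Both modes are implemented; `beta_mode = "fixed"` is
  used where a result is anchored to those SNRs.
* **Support placement** in models 4–5 is unstated; the default is the
  leading indices, with `support_positions = "random"` available.
* **Training size.**  The benchmark prose once fixes the training size at
  100, but every results table is indexed by $n \in \{40, 80\}$; `n_train`
  governs.
* **Nonzero threshold** for the counts is $|\hat\beta_j| > 10^{-10}$:
  soft-thresholding produces exact zeros, so this only guards float dust.
* **Problem sizes.**  The model-5 cells run with a $\tau$ grid coarsened
  to step 0.05 and 25 replicates by default in the acceptance runs, the
  low-dimensional cells with the full printed grids and 100 replicates.

What the generator does *not* emulate: heavy-tailed or heteroscedastic
errors, non-Gaussian designs, correlated noise, or measurement error in
the predictors.  Passing benchmark tests therefore demonstrates correct
implementation of the stated protocol, not robustness of the estimator on
real data.

## What reproduces and what does not

Running this implementation under the stated protocol reproduces the
low-dimensional benchmark structure: the model-1 adaptive-lasso cell at
$n = 80$ lands at the published value within Monte Carlo error (about
0.06 against a published 0.051), and the model-2 lqsso cell at $n = 40$
likewise (about 0.36–0.39 against 0.345).  Several published
high-dimensional quantities are, however, unattainable by *any* faithful
CV-tuned fit of this estimator:

* published relative prediction errors for models 4–5 at low
  signal-to-noise exceed the null-model bound
  ($\mathrm{RPE}(\hat\beta = 0) = \mathrm{SNR}$, e.g. $\approx 0.83$ for
  model 4 at $\sigma = 6$ versus a published 1.206) — a tuned estimator
  whose grid contains near-null fits cannot do worse than the null on
  average;
* a published median of 29 of 30 correct selections with about one false
  selection at $p = 1000$, $n = 80$, $\mathrm{SNR} \approx 0.6$ is far
  beyond what L1 selection can deliver at that sample size (this
  implementation, like a reference path solver on the same data, finds a
  median near 6–8).

The corresponding acceptance checks are implemented at their stated
tolerances and left failing rather than widened; the package reports what
the protocol actually yields.

## Oracle-property empirics

The supporting theory claims that with $\lambda_n/\sqrt n \to 0$ the
estimator's nonzero block is $\sqrt n$-consistent and asymptotically
normal, and that the selected support converges to the truth.  Because
lqsso weights are bounded (they do not grow on the truly-zero
coordinates the way adaptive-lasso weights do), the penalty at a rate
like $\lambda_n = n^{0.4}$ vanishes relative to the $\sqrt n$ noise
scale, and exact-support recovery probabilities stay near zero at
practical $n$; the test suite asserts only the monotone trend over
$n \in \{50, 200, 800\}$.  For the same reason the $\sqrt n$-scale
covariance of the nonzero block matches the full-design information block
$\sigma^2(C^{-1})_{AA}$ (measured relative Frobenius error 0.17 at
$n = 800$) rather than the oracle form $\sigma^2 C_{11}^{-1}$, which
would additionally require exact selection.  This is a real limitation of
sign-based bounded weights, not of the implementation.

## Gene-expression screening

For real-data use the package ships the standard two-stage screen:
`variance_screen()` keeps the $k_1$ most variable genes, then
`correlation_screen()` keeps the $k_2$ genes with the largest absolute
Pearson correlation with a target transcript (in the motivating
application, expression of TRIM32 in $n = 120$ rat eye samples, screened
$18975 \to 3000 \to 200$).  The screened matrix feeds `standardize_xy()`
directly.  The rat eye data are not bundled; any CSV expression matrix
reproduces the pipeline via `read_design()` or the command-line front end
in `inst/cli/lqsso.R`.

## Known limitations

* The lqsso penalty depends on the initial fit only through signs;
  near-zero initial estimates flip signs under resampling, so the
  selected $\tau$ can be unstable when many effects are tiny.
* With $p \ge n$ the $\tau$-grid endpoints produce effectively
  unpenalized sign groups (see the clamping note); they are retained for
  protocol fidelity but are rarely selected and are solved approximately
  during cross-validation.
* `run_experiment()` at model 5 with full grids is compute-intensive;
  the coarsened $\tau$ grid is the intended desk-scale setting.
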