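---
title: "Monte Carlo stabilized penalty selection: model, design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo stabilized penalty selection: model, design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnet)
```

## The problem

Penalized logistic regression with an $\ell_1$ (lasso) or elastic-net
penalty is the workhorse for building sparse biomarker signatures from
high-dimensional tabular data: for outcome $Y \in \{0,1\}$ and covariates
$x \in \mathbb{R}^p$,

$$\min_{\beta_0, \beta}\; -\frac{1}{n}\sum_{i=1}^n \left[ y_i(\beta_0 + x_i^\top\beta)
  - \log\!\left(1 + e^{\beta_0 + x_i^\top\beta}\right)\right]
  + \lambda \sum_{j=1}^p\left[\alpha|\beta_j| + \tfrac{1-\alpha}{2}\beta_j^2\right],$$

fit along a descending grid of $\lambda$ values (the solution path). The
set of predictors with nonzero coefficients at the chosen $\lambda$ — the
*signature* — and the model's predictive performance both hinge on that one
tuning constant, conventionally chosen by K-fold cross-validation (CV).

On small and moderate samples the CV optimum $\hat\lambda_{opt}$ is a
noisy, often *multimodal* random variable: rerunning the same CV with a
different fold split can move the selected signature from a handful of
predictors to dozens. Because the solution path is fixed given the training
data, all of that instability is instability of $\hat\lambda_{opt}$.

## The stabilized procedure

`mc_select()` repeats the K-fold CV $s$ times with fresh stratified splits
of the *same* training data, always scoring candidates on the *same*
full-data $\lambda$ grid, and stabilizes the draws
$\hat\lambda_{opt}^{(1)}, \dots, \hat\lambda_{opt}^{(s)}$:

* `median_lambda` (default): $\hat\lambda = \mathrm{median}_t\, \hat\lambda_{opt}^{(t)}$,
  taken on the raw $\lambda$ scale; for even $s$ the two central order
  statistics are averaged. The median is preferred over the mean because
  draw distributions are skewed and occasionally contain outlying runs.
* `mean_lambda`: the mean of the draws — an estimate of the conditional
  expectation of the CV optimum given the data.
* `median_loss_curve` / `mean_loss_curve`: stabilize the per-run criterion
  curves pointwise over the shared grid first, then optimize the combined
  curve.

The final model is refit on the full data at exactly $\hat\lambda$. Since
the median of grid values is generally off-grid for even $s$, the refit
descends the stored grid to the target value in a single warm-started fit;
coefficients are never interpolated, because interpolation does not
preserve the zero pattern that defines the signature. With $s = 1$ the
procedure is exactly a single CV run plus refit, which makes the
conventional approach a special case and the comparison between the two a
controlled one.

As $s$ grows the selected penalty converges to a functional of the data
alone (the median of the conditional distribution of the CV optimum), so
the run-to-run variance of the selection can only shrink; the practical
question, answered empirically by `sweep_s()`, is how large $s$ must be.
Fifty iterations suffice across all the packaged study scenarios.

### Tuning criterion

AUC is the sole tuning and reporting criterion for the binary-outcome
procedure (deviance is also implemented). Two per-$\lambda$ AUC curves are
possible: the fold-size-weighted **mean of per-fold AUCs** (grouped), and
the AUC of all folds' held-out scores **pooled** together. The default
(`grouped = "auto"`) uses fold averaging whenever every fold holds at
least ten observations of both classes and pools otherwise — the same
switching rule as the standard CV implementation, and the choice matters
more than it looks: per-fold AUCs on ten-observation folds are extremely
granular, so the fold-averaged curve is much noisier than the pooled one,
and that noise is precisely what makes the single-run selected penalty
multimodal and the reported criterion optimistic. Reproducing the
established tool's behaviour (including the size of its instability, which
is the problem this package exists to fix) therefore requires the grouped
form at $n = 100, k = 10$; `grouped = FALSE` gives the smoother pooled
variant. The one-standard-error rule takes its spread from the per-fold
AUCs where computable. Ties in the criterion break towards the larger
$\lambda$ (the sparser model). Folds are always stratified by outcome so
every fold carries both classes at $n = 100$.

One property of the AUC criterion worth knowing: under a *pure-noise*
outcome its CV curve is flat (the all-zero model scores exactly 0.5, and
every other grid point fluctuates around 0.5), so its argmax is essentially
arbitrary and null signatures are not particularly small. The deviance
criterion does retain a gradient towards parsimony under the null; if
false-positive control on potentially signal-free data matters, tune on
deviance or use the one-standard-error rule.

### Honest performance estimation

The CV criterion evaluated at the selected $\hat\lambda$ (the "internal CV"
AUC) is optimistically biased — the same folds both picked the winner and
scored it, a winner's-curse effect that is largest for weak signal and
small $n$. `nested_evaluate()` therefore wraps the *entire* selection
(including its inner CV) in an outer stratified K-fold loop: the selection
runs on each outer training part only, the refit model scores the held-out
fold, and all held-out scores pool into one AUC per repeat; the wrapper is
repeated `c_repeats` times with fresh outer splits and the mean and SD are
reported. Defaults are `k_outer = 5` and `c_repeats = 10`. A structural
audit trail (per-repeat fold assignments and per-fold training indices) is
returned so leakage-freedom is checkable, and is asserted in the tests.

## The synthetic study generator

`generate_dataset()` draws from a logistic model with five informative
standard-normal predictors, coefficient profile $(8,7,6,5,4)$ scaled by a
signal level $m$, intercept 0 (balanced classes); plus `m1` independent
standard-normal noise predictors; plus `m2` correlated surrogates
$\tilde X = \rho X_{parent} + \sqrt{1-\rho^2} Z$, half at $\rho = 0.5$ and
half at $\rho = 0.8$, parents cycling over the informative predictors (only
$X_1, X_2$ when `m2 = 4`). Surrogates have unit variance by construction.
Each training set is paired with an independent test set (default
$N = 10{,}000$), large enough that the test AUC of a fitted model is an
effectively external performance measure.

**Signal calibration.** The generator's linear predictor is scaled by a
fixed $\sqrt{2}$ calibration constant, i.e. the effective coefficients are
$\sqrt{2}\, m\,(8,7,6,5,4)$, so that the three canonical signal levels
$m = 0.04 / 0.07 / 0.15$ operate at generative AUCs of approximately
$0.70 / 0.80 / 0.92$ (the AUC of the true event probability against
outcomes drawn from it, estimated by `true_auc()`). These operating points
were fixed by quadrature on the induced case/control score distributions
and are what the packaged acceptance checks assert; without the
calibration constant the bare coefficient products would operate at
noticeably lower AUCs.

The generator emulates the correlation structure typical of omics panels —
informative features hidden among many irrelevant ones, with clusters of
surrogates tracking the true markers. It does **not** emulate heavy-tailed
or skewed marker distributions, batch effects, missingness, or
outcome-dependent sampling; conclusions from passing tests transfer to real
data only insofar as those features are absent or handled upstream.

## The 27-scenario study

`scenario_table()` crosses three signal levels ($m$), three training sizes
($n = 100/500/1000$) and three noise dimensions ($m_1 = 50/500/5000$ with
$m_2 = 4/40/400$ surrogates), numbered with signal outermost and noise
innermost.

Two replication protocols serve two different questions, and conflating
them buries the stability phenomenon:

* **Dataset replication** (`run_scenario()`): each replicate draws a fresh
  train/test pair, runs the selection at each requested $s$ (datasets
  shared across $s$ values, pairing the comparison), scores the refit
  model on the large test set, and optionally runs the outer wrapper.
  Summaries — median/MAD external AUC, median internal/outer optimism —
  then include sampling variation, which is the right frame for
  performance and bias questions. At $n = 100$ the between-dataset spread
  of the external AUC is around 3 AUC points for *any* $s$, so dataset
  replication cannot resolve the stabilization effect on selection.
* **Run replication** (`stability_sweep()`, `sweep_s()`): the training
  data are held fixed and the entire selection is rerun with fresh master
  seeds. The solution path is fixed given the data, so all run-to-run
  signature variation is fold-split noise — the quantity the Monte Carlo
  step suppresses, and the protocol under which the signature-size IPR-90
  (90th minus 10th percentile, linear-interpolation quantiles) collapses
  as $s$ grows while the single-run procedure stays erratic.

MADs are unscaled (no normal-consistency factor) so they read directly as
spread in AUC points.

### Problem sizes used by the packaged checks

The packaged acceptance suite runs the study at reduced scale, chosen once
as the package's own study conditions: a 50-point $\lambda$ grid
(`penalty_config(n_lambda = 50)`) over the data-derived range; 30
replicate datasets for the headline n=100 external-AUC scenarios and 20
for the large-$n$ one; 8–20 replicates for the wrapper-bias runs and 5–10
for the widest ($p \approx 5500$) scenarios; and fixed-dataset stability
sweeps of 4–20 runs per scenario. Full-scale settings (100-point grid, 100 replicates,
`c_repeats` up to 50) are plain configuration changes. At the reduced
scale the IPR-90 estimates for the widest scenarios are coarse (few order
statistics), but the contrast they are used for — stability at $s = 50$
versus $s = 1$ — is an order of magnitude larger than that coarseness.

## Numerical choices

* **Solver.** The path is fit by the coordinate-descent solver of
  **glmnet** (binomial family), with convergence threshold `1e-7` and
  bounded iterations; the package's own tests certify the solutions against
  direct convex minimization (smoothed-$|\cdot|$ BFGS oracle) to an
  objective gap below $10^{-6}$.
* **Grid.** Data-derived: $\lambda_{max}$ from the KKT condition on
  standardized predictors (the smallest $\lambda$ with an all-zero
  solution), log-spaced down to `lambda_min_ratio` $\cdot\,\lambda_{max}$
  (default $10^{-2}$ for $p > n$, else $10^{-4}$). The grid is computed
  once per training set and shared across all Monte Carlo repetitions, so
  all repetitions rank points on one fixed solution path.
* **Standardization.** Predictors are standardized internally before
  penalization (the penalty is scale-sensitive); coefficients are reported
  on the original scale.
* **Off-grid refits.** Exact refit at the target $\lambda$ (warm-started
  along the truncated grid), never interpolation.
* **Seeds.** Every stochastic entry point takes an explicit seed; master
  seeds spawn child seeds by a fixed mixing scheme (`derive_seeds()`), so
  Monte Carlo repetitions, wrapper repeats and replicate datasets are
  reproducible and order-independent, and all caller RNG state is
  restored.
* **Degenerate inputs.** Single-class outcomes are rejected
  (`"degenerate outcome"`); non-finite predictor entries are rejected at
  construction; single-class held-out folds under the AUC criterion are
  handled by pooling (they only drop out of the standard-error estimate);
  criterion ties break to the sparser model.

## Known limitations

* The binomial family only; survival, multinomial and Gaussian outcomes
  and non-convex penalties (e.g. SCAD) are out of scope, though nothing in
  the stabilization logic is family-specific.
* Bootstrap resampling of the data (in place of repeated fold splits) is
  not implemented.
* The one-standard-error rule is available (`lambda_1se`) but the
  stabilized optimum is the default recommendation: the sparser 1-SE
  signatures are more stable but measurably less predictive.
* AUC-criterion tuning has no parsimony gradient under a signal-free
  outcome (see above).
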