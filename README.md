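# mcnet — Monte Carlo stabilized penalty selection for penalized logistic regression

Sparse biomarker signatures are usually built with lasso / elastic-net
logistic regression, with the penalty parameter λ chosen by K-fold
cross-validation (CV). On small and moderate samples that choice is
unstable: rerunning the *same* CV with a different random fold split can
move the selected λ across a multimodal distribution and swing the
signature from a handful of predictors to dozens. Since the solution path

&nbsp;&nbsp;&nbsp;&nbsp;min over (β₀, β) of −(1/n) Σᵢ [ yᵢ(β₀ + xᵢᵀβ) − log(1 + exp(β₀ + xᵢᵀβ)) ] + λ Σⱼ [ α|βⱼ| + ½(1−α)βⱼ² ]

is fixed given the data, all of that instability lives in λ.

`mcnet` stabilizes the choice: repeat the K-fold CV **s** times with fresh
stratified splits on one fixed λ grid and take the **median** of the s
per-run optima as the final penalty (with s = 1 this is exactly the
conventional single-run procedure). It also provides a repeated outer CV
wrapper around the *entire* selection for honest performance estimates —
the internal CV criterion at the selected λ is optimistically biased —
plus the synthetic-data generator, stability metrics (signature-size
IPR-90, selection frequencies) and the 27-scenario study driver used to
characterize both procedures.

For whom: biostatisticians and ML practitioners building sparse
classifiers on omics / clinical panels who need the *composition* of the
model to be reproducible, not just its AUC.

## Worked example

```r
library(mcnet)

# one draw of the moderate-signal study scenario: n=100, 5 informative
# predictors, 50 noise predictors, 4 correlated surrogates, test set n=10000
sim <- generate_dataset(scenario_config(m = 0.07, n_train = 100,
                                        m1 = 50, m2 = 4, seed = 5))

# conventional single-run CV tuning  (s = 1)
g1 <- mc_select(sim$train, s = 1, k = 10, seed = 1)

# Monte Carlo stabilized selection   (s = 50)
g50 <- mc_select(sim$train, s = 50, k = 10, seed = 1)
g50
#> <mcnet_mc> s=50, strategy=median_lambda
#>   lambda_final=0.02183, signature size=30, internal CV auc=0.6901

external_auc(g50, sim$test)
#> [1] 0.7104716

# fold-split instability on this one dataset: rerun each procedure 10 times
sw <- stability_sweep(sim$train, s_values = c(1, 50), n_runs = 10, seed = 2)
sw
#> <mcnet_stability_sweep> 10 runs per s
#>   s ipr90 median_size
#>   1  26.5          27
#>  50   1.2          30

# honest performance of the whole s=50 procedure (no leakage)
nested_evaluate(sim$train, s = 50, k_outer = 5, c_repeats = 10, seed = 3)
#> <mcnet_outer> 10 repeats of 5-fold outer CV
#>   AUC 0.5734 (SD 0.0410); internal CV AUC at final lambda 0.6751
```

Reading: on this dataset the single-run procedure's signature size ranged
over an IPR-90 of ~27 predictors across ten reruns, while the s = 50
procedure's ranged over ~1 — same data, same solution path, same
predictive performance (external AUC ≈ 0.71 against the 0.80 generative
ceiling at this signal level). The internal CV AUC (≈ 0.69) sits above the
leak-free wrapper estimate (0.57): the wrapper removes the selection
optimism and, at n = 100, adds the conservatism of training its fold
models on 4/5 of the data — on a single weak-signal dataset the honest
estimate can sit well below the external AUC, which is why it is reported
with its SD over repeats.

The signal levels m = 0.04 / 0.07 / 0.15 are calibrated to generative AUCs
of ≈ 0.70 / 0.80 / 0.92 (`true_auc()`); the methods vignette
(`vignettes/mcnet-methods.Rmd`) documents the calibration, the pooling and
tie-breaking conventions, the two replication protocols (dataset-level for
performance/bias, run-level for stability), and known limitations.

## CLI

```sh
Rscript inst/cli/mcnet.R fit      --data d.csv --outcome y --s 50 --seed 7 --out model.json
Rscript inst/cli/mcnet.R evaluate --data d.csv --outcome y --s 50 --k-outer 5 --repeats 10 --out report.json
Rscript inst/cli/mcnet.R simulate --m 0.07 --n 100 --m1 50 --m2 4 --out train.csv
```
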