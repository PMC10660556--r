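#' Combine Monte Carlo tuning-parameter draws into one penalty value
#'
#' The stabilization step applied to the `s` per-run optima: the median (the
#' headline rule), or the mean (an estimate of the conditional expectation
#' of the CV optimum given the data). Medians are taken on the raw lambda
#' scale; for even `s` the two central order statistics are averaged.
#'
#' @param draws Numeric vector of per-run lambda optima.
#' @param strategy `"median_lambda"` or `"mean_lambda"`.
#' @return Single penalty value.
#' @examples
#' combine_draws(c(.1, .2, .3, .4, 10))  # 0.3 — robust to the outlier run
#' @export
combine_draws <- function(draws, strategy = c("median_lambda", "mean_lambda")) {
  strategy <- match.arg(strategy)
  stopifnot(length(draws) >= 1L, all(is.finite(draws)))
  switch(strategy,
         median_lambda = stats::median(draws),
         mean_lambda = mean(draws))
}

#' Monte Carlo stabilized penalty selection (MCglmnet)
#'
#' Repeats K-fold cross-validation `s` times with fresh random splits of the
#' same training data, then stabilizes: under `"median_lambda"` (default)
#' the final penalty is the median of the `s` per-run optima; under
#' `"mean_lambda"` their mean; under `"median_loss_curve"` /
#' `"mean_loss_curve"` the `s` criterion curves are combined pointwise over
#' the shared grid first and the final penalty optimizes the combined
#' curve. The final model is refit on the full data at the stabilized
#' penalty and its nonzero coefficients form the signature.
#'
#' The lambda grid is computed **once** from the full data and shared by all
#' `s` repetitions, so every repetition works on the same solution path and
#' the selected variables are a deterministic function of the final lambda.
#' With `s = 1` the procedure reduces exactly to a single cross-validation
#' run plus refit.
#'
#' @param data An [mc_dataset()].
#' @param penalty A [penalty_config()].
#' @param s Number of Monte Carlo repetitions (>= 1).
#' @param k Folds for the inner cross-validation.
#' @param strategy Stabilization rule; see Details.
#' @param seed Master seed; `s` child seeds are derived by a fixed scheme
#'   ([derive_seeds()]), one per repetition.
#' @param lambdas Optional pre-computed grid (defaults to the full-data
#'   path grid).
#' @param criterion Tuning criterion, `"auc"` (default) or `"deviance"`.
#' @param grouped AUC fold-averaging rule, passed to [cv_curve()].
#' @param keep_runs Keep the `s` full `mcnet_cv` objects (memory-heavy;
#'   default keeps only draws and curves).
#' @return Object of class `mcnet_mc`: `s`, `lambda_draws`, `strategy`,
#'   `lambda_final`, `final_fit` (list `a0`, `beta`), `signature` (named
#'   index vector), `signature_size`, `seeds`, `internal_cv_criterion` (the
#'   criterion value the tuning procedure reports: the per-run achieved
#'   optima combined with the same rule as the lambdas — the optimistically
#'   biased "internal CV" performance number), `curves` (L x s criterion
#'   matrix), `lambdas`, `path`.
#' @references The procedure and its rationale are described in the methods
#'   vignette: `vignette("mcnet-methods")`.
#' @export
mc_select <- function(data, penalty = penalty_config(), s = 50L, k = 10L,
                      strategy = c("median_lambda", "mean_lambda",
                                   "median_loss_curve", "mean_loss_curve"),
                      seed = 1L, lambdas = NULL,
                      criterion = c("auc", "deviance"), grouped = "auto",
                      keep_runs = FALSE) {
  strategy <- match.arg(strategy)
  criterion <- match.arg(criterion)
  s <- as.integer(s)
  if (s < 1L) stop("s must be at least 1")
  path <- fit_path(data, penalty, lambdas = lambdas)
  grid <- path$lambdas
  L <- length(grid)
  seeds <- derive_seeds(seed, s, salt = 1L)
  draws <- numeric(s)
  curves <- matrix(NA_real_, L, s)
  runs <- if (keep_runs) vector("list", s) else NULL
  for (t in seq_len(s)) {
    folds <- make_folds(data, k, seeds[t])
    run <- cv_curve(data, penalty, folds, grid, criterion, grouped = grouped)
    draws[t] <- run$lambda_opt
    curves[, t] <- run$criterion_mean
    if (keep_runs) runs[[t]] <- run
  }
  if (strategy %in% c("median_lambda", "mean_lambda")) {
    lambda_final <- combine_draws(draws, strategy)
  } else {
    comb <- if (strategy == "median_loss_curve") {
      apply(curves, 1L, stats::median)
    } else {
      rowMeans(curves)
    }
    best <- if (criterion == "auc") max(comb) else min(comb)
    lambda_final <- grid[which(comb == best)[1]]   # ties -> largest lambda
  }
  cf <- coef_at(path, lambda_final)
  sig <- which(cf$beta != 0)
  names(sig) <- path$feature_names[sig]
  # The criterion value the tuning procedure itself reports: each CV run
  # reports its achieved optimum, and the runs are combined with the same
  # rule that combines the lambdas (for the curve strategies, the optimum
  # of the combined curve). This is the "internal CV" performance number —
  # deliberately the optimistically biased one that the outer wrapper
  # exists to correct, since the same folds both picked and scored it.
  per_run_opt <- if (criterion == "auc") {
    apply(curves, 2L, max)
  } else {
    apply(curves, 2L, min)
  }
  internal <- switch(strategy,
    median_lambda = stats::median(per_run_opt),
    mean_lambda = mean(per_run_opt),
    if (criterion == "auc") max(comb) else min(comb))
  structure(
    list(s = s, lambda_draws = draws, strategy = strategy,
         lambda_final = lambda_final, final_fit = cf,
         signature = sig, signature_size = length(sig),
         seeds = seeds, criterion_name = criterion,
         internal_cv_criterion = internal,
         curves = curves, lambdas = grid,
         feature_names = path$feature_names, path = path,
         runs = runs),
    class = "mcnet_mc"
  )
}

#' @export
print.mcnet_mc <- function(x, ...) {
  cat(sprintf(
    "<mcnet_mc> s=%d, strategy=%s\n  lambda_final=%.5g, signature size=%d, internal CV %s=%.4f\n",
    x$s, x$strategy, x$lambda_final, x$signature_size,
    x$criterion_name, x$internal_cv_criterion))
  if (x$signature_size > 0 && x$signature_size <= 25) {
    cat("  signature:", paste(names(x$signature), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Distribution of the Monte Carlo lambda draws
#'
#' Quantiles of the `s` per-run optima and log-scale histogram counts, the
#' raw material for instability diagnostics (multimodal draw distributions
#' are the signature of an unstable single-run selection).
#'
#' @param sel An `mcnet_mc`.
#' @param probs Quantile probabilities.
#' @param breaks Passed to [graphics::hist()] binning (on `log(lambda)`).
#' @return List with `quantiles`, `log_breaks`, `counts`.
#' @export
lambda_draw_distribution <- function(sel, probs = c(0, .1, .25, .5, .75, .9, 1),
                                     breaks = "Sturges") {
  stopifnot(inherits(sel, "mcnet_mc"))
  d <- sel$lambda_draws
  h <- graphics::hist(log(d), breaks = breaks, plot = FALSE)
  list(quantiles = stats::quantile(d, probs, type = 7),
       log_breaks = h$breaks, counts = h$counts)
}
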