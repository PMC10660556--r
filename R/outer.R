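#' Repeated outer cross-validation around the full selection procedure
#'
#' Wraps the *entire* Monte Carlo tuning procedure (including its own inner
#' cross-validation) in an outer stratified K-fold loop: for each outer
#' fold, [mc_select()] runs on the training part only and the refit model
#' scores the held-out part; the held-out scores of all folds are pooled
#' into one AUC per repeat. Repeating the wrapper `c_repeats` times and
#' reporting the mean and SD gives a near-unbiased estimate of the
#' performance of the deployed model — unlike the internal CV criterion at
#' the selected penalty, which is optimistically biased because the same
#' folds picked the penalty.
#'
#' @param data An [mc_dataset()].
#' @param penalty A [penalty_config()].
#' @param s Monte Carlo repetitions for each inner selection.
#' @param k_inner Inner CV folds.
#' @param k_outer Outer folds per repeat.
#' @param c_repeats Number of outer-CV repeats.
#' @param strategy Stabilization rule, as in [mc_select()].
#' @param seed Master seed; repeat- and fold-level seeds are derived from
#'   it.
#' @param criterion Tuning/reporting criterion.
#' @return Object of class `mcnet_outer`: `per_repeat_auc`, `auc_mean`,
#'   `auc_sd`, `internal_cv_auc` (the reported internal-CV criterion of the
#'   full-data selection), `selection` (the full-data `mcnet_mc` — the model
#'   the procedure actually delivers), `c_repeats`, `k_outer`, `seeds`, and
#'   an `audit` list with each repeat's fold assignment.
#' @export
nested_evaluate <- function(data, penalty = penalty_config(), s = 50L,
                            k_inner = 10L, k_outer = 5L, c_repeats = 10L,
                            strategy = "median_lambda", seed = 1L,
                            criterion = "auc") {
  stopifnot(inherits(data, "mcnet_dataset"), k_outer >= 2)
  n <- nrow(data$X)
  rep_seeds <- derive_seeds(seed, c_repeats, salt = 2L)
  per_repeat <- numeric(c_repeats)
  audit <- vector("list", c_repeats)
  for (r in seq_len(c_repeats)) {
    folds <- make_folds(data, k_outer, rep_seeds[r])
    fold_seeds <- derive_seeds(rep_seeds[r], k_outer, salt = 3L)
    scores <- numeric(n)
    train_idx <- vector("list", k_outer)
    for (j in seq_len(k_outer)) {
      hold <- folds$assignment == j
      train_idx[[j]] <- which(!hold)
      sel <- mc_select(dataset_subset(data, !hold), penalty, s = s,
                       k = k_inner, strategy = strategy,
                       seed = fold_seeds[j], criterion = criterion)
      scores[hold] <- sel$final_fit$a0 +
        as.numeric(data$X[hold, , drop = FALSE] %*% sel$final_fit$beta)
    }
    per_repeat[r] <- auc(scores, data$y)
    audit[[r]] <- list(assignment = folds$assignment, train_idx = train_idx)
  }
  full_sel <- mc_select(data, penalty, s = s, k = k_inner,
                        strategy = strategy,
                        seed = derive_seeds(seed, 1, salt = 4L),
                        criterion = criterion)
  structure(
    list(per_repeat_auc = per_repeat,
         auc_mean = mean(per_repeat),
         auc_sd = if (c_repeats > 1) stats::sd(per_repeat) else NA_real_,
         internal_cv_auc = full_sel$internal_cv_criterion,
         selection = full_sel,
         c_repeats = c_repeats, k_outer = k_outer,
         seeds = rep_seeds, audit = audit),
    class = "mcnet_outer"
  )
}

#' @export
print.mcnet_outer <- function(x, ...) {
  cat(sprintf(
    "<mcnet_outer> %d repeats of %d-fold outer CV\n  AUC %.4f (SD %.4f); internal CV AUC at final lambda %.4f\n",
    x$c_repeats, x$k_outer, x$auc_mean, x$auc_sd, x$internal_cv_auc))
  invisible(x)
}

#' Optimism of internal and outer CV performance estimates
#'
#' Subtracts the external (large independent test set) AUC from the AUC the
#' internal tuning CV reports at the selected penalty, and from the outer-
#' wrapper estimate. Positive values are optimistic bias.
#'
#' @param report An `mcnet_outer`.
#' @param external_auc External test-set AUC of the full-data model.
#' @return List with `internal_bias` and `outer_bias`.
#' @export
bias_report <- function(report, external_auc) {
  stopifnot(inherits(report, "mcnet_outer"))
  list(internal_bias = report$internal_cv_auc - external_auc,
       outer_bias = report$auc_mean - external_auc)
}
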