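#' Stratified K-fold split
#'
#' Assigns each observation to one of `k` folds, stratified by the binary
#' outcome so that every fold's class balance matches the overall prevalence
#' to within one observation. Deterministic given `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param data An [mc_dataset()] (or a bare 0/1 vector).
#' @param k Number of folds (>= 2, <= n).
#' @param seed Integer seed.
#' @return Object of class `mcnet_folds`: `k`, `assignment` (fold labels
#'   1..k), `seed`.
#' @export
make_folds <- function(data, k, seed) {
  y <- if (inherits(data, "mcnet_dataset")) data$y else as.integer(data)
  n <- length(y)
  k <- as.integer(k)
  if (k > n) stop("k must not exceed the number of observations")
  if (k < 2L) stop("k must be at least 2")
  assignment <- integer(n)
  with_seed(seed, {
    # Consecutive fold labels (mod k) keep per-class fold sizes within one
    # observation; the cross-class offset lets small classes still cover
    # all folds (so k may exceed a class count, up to k = n).
    offset <- sample.int(k, 1L) - 1L
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      assignment[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- offset + length(idx)
    }
  })
  if (length(unique(assignment)) < k) {
    stop("empty fold produced; reduce k")
  }
  structure(list(k = k, assignment = assignment, seed = as.integer(seed)),
            class = "mcnet_folds")
}

#' One cross-validation pass over the penalty grid
#'
#' For each fold, fits the solution path on the remaining data at the
#' *shared* grid `lambdas` and scores the held-out observations. Under the
#' AUC criterion the per-lambda curve is, by default (`grouped = "auto"`),
#' the fold-size-weighted mean of per-fold AUCs whenever every fold holds
#' at least ten observations of both classes, and otherwise the AUC of all
#' folds' held-out scores pooled together — the same switching rule as the
#' reference cross-validation tool, which matters because the fold-averaged
#' curve is noticeably noisier and that noise is what drives both the
#' instability of the selected penalty and the optimism of the reported
#' criterion. Deviance is always the pooled mean. The per-fold criterion
#' values (where computable) supply the standard error used by the
#' one-standard-error rule.
#'
#' The returned `lambda_opt` is the grid value with the best pooled
#' criterion; ties break towards the largest lambda (most parsimonious
#' model). `lambda_1se` is the largest lambda whose criterion is within one
#' standard error of the optimum.
#'
#' @param data An [mc_dataset()].
#' @param penalty A [penalty_config()].
#' @param folds An [make_folds()] plan.
#' @param lambdas Descending penalty grid, fixed in advance (shared across
#'   folds and, upstream, across Monte Carlo repetitions).
#' @param criterion `"auc"` (maximized) or `"deviance"` (minimized).
#' @param grouped `"auto"` (fold-averaged AUC when folds are large enough,
#'   else pooled), `TRUE` (always fold-averaged; errors on degenerate
#'   folds), or `FALSE` (always pooled).
#' @return Object of class `mcnet_cv`: `lambdas`, `criterion_mean` (the
#'   per-lambda criterion curve), `criterion_se`, `fold_criterion` (k x L
#'   matrix, possibly with NAs for degenerate folds under AUC),
#'   `criterion_name`, `grouped` (whether fold averaging was used),
#'   `lambda_opt`, `lambda_1se`, `fold_plan`.
#' @export
cv_curve <- function(data, penalty, folds, lambdas,
                     criterion = c("auc", "deviance"), grouped = "auto") {
  criterion <- match.arg(criterion)
  stopifnot(inherits(data, "mcnet_dataset"), inherits(folds, "mcnet_folds"))
  n <- nrow(data$X)
  stopifnot(length(folds$assignment) == n)
  L <- length(lambdas)
  pred <- matrix(NA_real_, n, L)      # held-out linear predictors
  for (i in seq_len(folds$k)) {
    hold <- folds$assignment == i
    fit <- glmnet::glmnet(
      data$X[!hold, , drop = FALSE], data$y[!hold], family = "binomial",
      alpha = penalty$alpha, lambda = lambdas,
      standardize = penalty$standardize,
      thresh = penalty$thresh, maxit = penalty$maxit
    )
    ph <- stats::predict(fit, data$X[hold, , drop = FALSE], type = "link")
    if (ncol(ph) < L) {  # defensive: solver returned a truncated path
      ph <- cbind(ph, matrix(ph[, ncol(ph)], nrow(ph), L - ncol(ph)))
    }
    pred[hold, ] <- ph[, seq_len(L), drop = FALSE]
  }
  y <- data$y
  fold_crit <- matrix(NA_real_, folds$k, L)
  for (i in seq_len(folds$k)) {
    hold <- folds$assignment == i
    if (criterion == "auc") {
      if (length(unique(y[hold])) == 2L) {
        fold_crit[i, ] <- .auc_cols(pred[hold, , drop = FALSE], y[hold])
      }                                  # single-class fold: skipped for SE
    } else {
      fold_crit[i, ] <- .deviance_cols(pred[hold, , drop = FALSE], y[hold])
    }
  }
  fold_n <- tabulate(folds$assignment, folds$k)
  use_grouped <- if (criterion != "auc") {
    FALSE
  } else if (identical(grouped, "auto")) {
    min(fold_n) >= 10 && !anyNA(fold_crit)
  } else {
    isTRUE(grouped)
  }
  if (use_grouped && anyNA(fold_crit)) {
    stop("grouped AUC requested but some fold held a single class")
  }
  pooled <- if (use_grouped) {
    as.numeric(fold_n %*% fold_crit) / sum(fold_n)
  } else if (criterion == "auc") {
    .auc_cols(pred, y)
  } else {
    .deviance_cols(pred, y)
  }
  k_used <- colSums(!is.na(fold_crit))
  crit_se <- apply(fold_crit, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(k_used, 1))
  best <- if (criterion == "auc") max(pooled) else min(pooled)
  opt_i <- which(pooled == best)[1]     # grid is descending: first = largest
  se_opt <- crit_se[opt_i]
  if (!is.finite(se_opt)) se_opt <- 0
  ok_1se <- if (criterion == "auc") pooled >= best - se_opt else pooled <= best + se_opt
  structure(
    list(lambdas = lambdas, criterion_mean = pooled, criterion_se = crit_se,
         fold_criterion = fold_crit, criterion_name = criterion,
         grouped = use_grouped,
         lambda_opt = lambdas[opt_i], lambda_1se = lambdas[which(ok_1se)[1]],
         fold_plan = folds),
    class = "mcnet_cv"
  )
}

#' @export
print.mcnet_cv <- function(x, ...) {
  cat(sprintf(
    "<mcnet_cv> %d-fold, criterion=%s; lambda_opt=%.5g (%s=%.4f), lambda_1se=%.5g\n",
    x$fold_plan$k, x$criterion_name, x$lambda_opt,
    x$criterion_name,
    x$criterion_mean[which(x$lambdas == x$lambda_opt)[1]], x$lambda_1se))
  invisible(x)
}

#' Serialize a CV run to JSON
#'
#' Grid, criterion curve, optima and the fold seed — enough to audit and
#' reproduce a tuning run.
#'
#' @param run An `mcnet_cv`.
#' @param path Output file.
#' @export
write_cv_json <- function(run, path) {
  out <- list(
    lambdas = run$lambdas, criterion = run$criterion_mean,
    criterion_se = run$criterion_se, criterion_name = run$criterion_name,
    lambda_opt = run$lambda_opt, lambda_1se = run$lambda_1se,
    k = run$fold_plan$k, seed = run$fold_plan$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
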