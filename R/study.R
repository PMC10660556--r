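#' Run replicate simulations of one study scenario
#'
#' For each replicate: generate an independent training/test pair under
#' `cfg`, run the Monte Carlo selection for every `s` in `s_values` (the
#' same datasets are shared across `s` values, pairing the comparison and
#' reducing between-`s` sampling noise), and score the refit model on the
#' large test set. Optionally, run the repeated outer cross-validation
#' wrapper (at `wrapper_s` Monte Carlo iterations) on the first
#' `wrapper_reps` replicates to estimate the optimism of the internal CV
#' criterion versus the outer wrapper.
#'
#' Replicates that fail (e.g. a degenerate simulated outcome) are dropped
#' with a warning and counted in `n_failed` — never silently.
#'
#' @param cfg A [scenario_config()]; its `seed` is the replicate master
#'   seed.
#' @param s_values Monte Carlo iteration counts to compare (always include
#'   1 to benchmark the single-run procedure).
#' @param n_replicates Number of replicate datasets.
#' @param penalty A [penalty_config()].
#' @param k_inner,k_outer Inner/outer fold counts.
#' @param c_repeats Outer-wrapper repeats per replicate.
#' @param wrapper Run the outer wrapper? (Costs `k_outer * wrapper_s` extra
#'   CV runs per replicate.)
#' @param wrapper_s `s` used inside the wrapper (default: the largest of
#'   `s_values`).
#' @param wrapper_reps How many replicates get the wrapper.
#' @param strategy Stabilization rule.
#' @param progress Print one line per replicate.
#' @return Object of class `mcnet_study`: `results` (one row per replicate
#'   x s: `lambda_final`, `signature_size`, `external_auc`,
#'   `internal_cv_auc`), `wrapper` (one row per wrapped replicate:
#'   `outer_auc`, `external_auc`, `internal_bias`, `outer_bias`),
#'   `summary` (per-s median/MAD external AUC and signature-size IPR-90),
#'   `n_failed`, `config`.
#' @export
run_scenario <- function(cfg, s_values = c(1L, 50L), n_replicates = 30L,
                         penalty = penalty_config(), k_inner = 10L,
                         k_outer = 5L, c_repeats = 1L, wrapper = FALSE,
                         wrapper_s = max(s_values),
                         wrapper_reps = n_replicates,
                         strategy = "median_lambda", progress = FALSE) {
  stopifnot(inherits(cfg, "mcnet_scenario"), n_replicates >= 1)
  s_values <- sort(unique(as.integer(s_values)))
  rep_seeds <- derive_seeds(cfg$seed, n_replicates, salt = 10L)
  rows <- list()
  wrows <- list()
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      cfg_r <- cfg
      cfg_r$seed <- rep_seeds[r]
      sim <- generate_dataset(cfg_r)
      sels <- lapply(s_values, function(s_i) {
        mc_select(sim$train, penalty, s = s_i, k = k_inner,
                  strategy = strategy,
                  seed = derive_seeds(rep_seeds[r], 1, salt = 20L + s_i))
      })
      rr <- data.frame(
        replicate = r, s = s_values,
        lambda_final = vapply(sels, `[[`, numeric(1), "lambda_final"),
        signature_size = vapply(sels, `[[`, numeric(1), "signature_size"),
        external_auc = vapply(sels, external_auc, numeric(1), test = sim$test),
        internal_cv_auc = vapply(sels, `[[`, numeric(1),
                                 "internal_cv_criterion")
      )
      wr <- NULL
      if (wrapper && r <= wrapper_reps) {
        rep_out <- nested_evaluate(
          sim$train, penalty, s = wrapper_s, k_inner = k_inner,
          k_outer = k_outer, c_repeats = c_repeats, strategy = strategy,
          seed = derive_seeds(rep_seeds[r], 1, salt = 30L)
        )
        ext_w <- rr$external_auc[match(wrapper_s, rr$s)]
        if (is.na(ext_w)) ext_w <- external_auc(rep_out$selection, sim$test)
        b <- bias_report(rep_out, ext_w)
        wr <- data.frame(replicate = r, s = wrapper_s,
                         outer_auc = rep_out$auc_mean,
                         internal_cv_auc = rep_out$internal_cv_auc,
                         external_auc = ext_w,
                         internal_bias = b$internal_bias,
                         outer_bias = b$outer_bias)
      }
      list(rr = rr, wr = wr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res$rr
      if (!is.null(res$wr)) wrows[[length(wrows) + 1L]] <- res$wr
    }
    if (progress) {
      message(sprintf("replicate %d/%d done", r, n_replicates))
    }
  }
  results <- do.call(rbind, rows)
  wrapper_df <- if (length(wrows)) do.call(rbind, wrows) else NULL
  summ <- do.call(rbind, lapply(split(results, results$s), function(d) {
    data.frame(s = d$s[1],
               n = nrow(d),
               external_auc_median = stats::median(d$external_auc),
               external_auc_mad = stats::mad(d$external_auc, constant = 1),
               internal_cv_auc_median = stats::median(d$internal_cv_auc),
               signature_size_median = stats::median(d$signature_size),
               ipr90 = if (nrow(d) >= 2) ipr90(d$signature_size) else NA_real_)
  }))
  rownames(summ) <- NULL
  structure(
    list(results = results, wrapper = wrapper_df, summary = summ,
         n_failed = n_failed, config = cfg, s_values = s_values),
    class = "mcnet_study"
  )
}

#' @export
print.mcnet_study <- function(x, ...) {
  cat(sprintf("<mcnet_study> m=%.2f n=%d m1=%d m2=%d; %d replicates (%d failed)\n",
              x$config$m, x$config$n_train, x$config$m1, x$config$m2,
              max(x$results$replicate), x$n_failed))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$wrapper)) {
    cat(sprintf("  wrapper (%d replicates): median internal bias %+.3f, median outer bias %+.3f\n",
                nrow(x$wrapper), stats::median(x$wrapper$internal_bias),
                stats::median(x$wrapper$outer_bias)))
  }
  invisible(x)
}

#' Selection stability across replicate runs on a fixed dataset
#'
#' The stability protocol: hold the training data fixed and rerun the
#' entire selection `n_runs` times with different master seeds, for each
#' `s` in `s_values`. Because the solution path is fixed given the data,
#' all run-to-run variation in the signature comes from the random fold
#' splits — exactly the noise source the Monte Carlo stabilization
#' suppresses. Contrast with [run_scenario()], which replicates *datasets*
#' and therefore mixes sampling variation into every summary.
#'
#' @param data An [mc_dataset()] (typically one scenario draw).
#' @param s_values Monte Carlo iteration counts to compare.
#' @param n_runs Replicate selections per `s`.
#' @param penalty A [penalty_config()].
#' @param k Inner CV folds.
#' @param seed Master seed (one child seed per run).
#' @param strategy Stabilization rule.
#' @return Object of class `mcnet_stability_sweep`: `sizes` (n_runs x
#'   length(s_values) matrix of signature sizes), `lambda_finals` (same
#'   shape), `ipr90` (per-s IPR-90 of the sizes), `s_values`.
#' @export
stability_sweep <- function(data, s_values = c(1L, 50L), n_runs = 20L,
                            penalty = penalty_config(), k = 10L, seed = 1L,
                            strategy = "median_lambda") {
  stopifnot(inherits(data, "mcnet_dataset"), n_runs >= 2)
  s_values <- sort(unique(as.integer(s_values)))
  grid <- fit_path(data, penalty)$lambdas   # one fixed solution path
  run_seeds <- derive_seeds(seed, n_runs, salt = 5L)
  sizes <- matrix(NA_real_, n_runs, length(s_values),
                  dimnames = list(NULL, paste0("s", s_values)))
  lams <- sizes
  for (r in seq_len(n_runs)) {
    for (j in seq_along(s_values)) {
      sel <- mc_select(data, penalty, s = s_values[j], k = k,
                       strategy = strategy, seed = run_seeds[r],
                       lambdas = grid)
      sizes[r, j] <- sel$signature_size
      lams[r, j] <- sel$lambda_final
    }
  }
  structure(
    list(sizes = sizes, lambda_finals = lams,
         ipr90 = apply(sizes, 2L, ipr90), s_values = s_values,
         n_runs = n_runs),
    class = "mcnet_stability_sweep"
  )
}

#' @export
print.mcnet_stability_sweep <- function(x, ...) {
  cat(sprintf("<mcnet_stability_sweep> %d runs per s\n", x$n_runs))
  print(data.frame(s = x$s_values, ipr90 = unname(x$ipr90),
                   median_size = apply(x$sizes, 2, stats::median)),
        row.names = FALSE)
  invisible(x)
}

#' Signature-size stability versus the number of Monte Carlo iterations
#'
#' Generates one dataset under `cfg` and runs [stability_sweep()] on it:
#' the IPR-90 of the signature size per `s`, the curve showing fold-split
#' instability dropping as the Monte Carlo stabilization deepens.
#'
#' @inheritParams run_scenario
#' @param n_replicates Replicate method runs per `s` (on the one dataset).
#' @return Data frame with columns `s` and `ipr90`.
#' @export
sweep_s <- function(cfg, s_values = c(1L, 10L, 20L, 50L), n_replicates = 30L,
                    penalty = penalty_config(), k_inner = 10L, ...) {
  sim <- generate_dataset(cfg)
  sw <- stability_sweep(sim$train, s_values = s_values,
                        n_runs = max(n_replicates, 2L), penalty = penalty,
                        k = k_inner, seed = cfg$seed, ...)
  data.frame(s = sw$s_values, ipr90 = unname(sw$ipr90))
}
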