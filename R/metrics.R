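#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUC with ties counted one half, i.e.
#' \eqn{P(S_1 > S_0) + \frac{1}{2}P(S_1 = S_0)} for a random case/control
#' score pair. Invariant under strictly increasing score transforms.
#'
#' @param scores Numeric score vector (higher = more case-like).
#' @param labels Binary 0/1 outcome vector.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 0, 1, 1))   # 1
#' auc(c(1, 1, 2), c(0, 1, 1))         # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)               # midranks handle ties at weight 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * as.numeric(n0))
}

# Column-wise AUC for a score matrix (one column per lambda); NA-free input.
.auc_cols <- function(S, labels) {
  apply(S, 2L, auc, labels = labels)
}

# Pooled mean binomial deviance of linear predictors eta against y.
.deviance_cols <- function(S, labels) {
  apply(S, 2L, function(eta) {
    2 * mean(log1pexp(eta) - labels * eta)
  })
}

#' Inter-percentile range of the signature size (IPR-90)
#'
#' The 90th minus the 10th percentile, the stability measure used to track
#' how much the number of selected predictors varies across replicate runs.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the value depends on this convention, which
#' is therefore fixed and documented.
#'
#' @param sizes Numeric vector (length >= 2) of signature sizes.
#' @return Non-negative scalar.
#' @examples
#' ipr90(1:11)  # 8
#' @export
ipr90 <- function(sizes) {
  if (length(sizes) < 2L) stop("need at least two values")
  q <- stats::quantile(sizes, c(0.1, 0.9), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Replicate-level location and spread
#'
#' Median, unscaled MAD (median absolute deviation from the median, with no
#' normal-consistency factor, so values read directly as raw spread in the
#' units of the input), mean and SD.
#'
#' @param values Numeric vector (length >= 1).
#' @return Named numeric vector `(median, mad, mean, sd)`; `sd` is `NA` for
#'   a single value.
#' @examples
#' replicate_summary(c(1, 2, 3, 4, 100))  # median 3, mad 1
#' @export
replicate_summary <- function(values) {
  stopifnot(length(values) >= 1L)
  c(median = stats::median(values),
    mad = stats::mad(values, constant = 1),
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else NA_real_)
}

#' Signature stability report across replicate runs
#'
#' Summarizes a collection of signatures (index sets of selected
#' predictors): the distribution of signature sizes, its IPR-90, and the
#' per-feature selection frequency.
#'
#' @param signatures List of integer index vectors (one per replicate run).
#' @param p Number of predictors (for the frequency table).
#' @param feature_names Optional feature labels.
#' @return Object of class `mcnet_stability` with `signature_sizes`,
#'   `ipr90`, `selection_frequency`, and `size_quantiles`
#'   (min/q1/median/mean/q3/max).
#' @export
stability_report <- function(signatures, p, feature_names = NULL) {
  stopifnot(is.list(signatures), length(signatures) >= 2L)
  sizes <- vapply(signatures, length, integer(1))
  freq <- numeric(p)
  for (sig in signatures) freq[sig] <- freq[sig] + 1
  freq <- freq / length(signatures)
  if (!is.null(feature_names)) names(freq) <- feature_names
  qs <- unname(stats::quantile(sizes, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  structure(
    list(signature_sizes = sizes,
         ipr90 = ipr90(sizes),
         selection_frequency = freq,
         size_quantiles = c(min = qs[1], q1 = qs[2], median = qs[3],
                            mean = mean(sizes), q3 = qs[4], max = qs[5])),
    class = "mcnet_stability"
  )
}

#' @export
print.mcnet_stability <- function(x, ...) {
  cat("<mcnet_stability>\n")
  cat(sprintf("  runs: %d, IPR-90 of signature size: %.1f\n",
              length(x$signature_sizes), x$ipr90))
  cat("  size quantiles:\n")
  print(round(x$size_quantiles, 2))
  invisible(x)
}
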