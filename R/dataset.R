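#' Construct a modelling dataset
#'
#' Bundles a numeric predictor matrix with a binary outcome and per-feature
#' metadata. This is the container consumed by [fit_path()], [cv_curve()],
#' [mc_select()] and [nested_evaluate()].
#'
#' @param X Numeric matrix, one row per observation, one column per
#'   predictor. All entries must be finite.
#' @param y Binary outcome vector (0/1, logical, or a two-level factor);
#'   both classes must be present.
#' @param feature_names Optional character vector of predictor labels;
#'   defaults to `colnames(X)` or `V1..Vp`.
#' @param is_informative Optional logical vector flagging truly informative
#'   predictors (simulated data only).
#' @return An object of class `mcnet_dataset` with elements `X`, `y`,
#'   `feature_names`, `is_informative`.
#' @examples
#' d <- mc_dataset(matrix(rnorm(40), 20, 2), rep(0:1, 10))
#' d
#' @export
mc_dataset <- function(X, y, feature_names = NULL, is_informative = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.factor(y)) {
    stopifnot(nlevels(y) == 2L)
    y <- as.integer(y) - 1L
  }
  y <- as.integer(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("need at least two observations")
  if (p < 1L) stop("need at least one predictor")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary (0/1)")
  if (!all(is.finite(X))) stop("X contains missing or non-finite values")
  if (length(unique(y)) < 2L) stop("degenerate outcome: y contains a single class")
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("V", seq_len(p))
  }
  stopifnot(length(feature_names) == p)
  colnames(X) <- feature_names
  if (!is.null(is_informative)) stopifnot(length(is_informative) == p)
  structure(
    list(X = X, y = y, feature_names = feature_names,
         is_informative = is_informative),
    class = "mcnet_dataset"
  )
}

#' @export
print.mcnet_dataset <- function(x, ...) {
  cat(sprintf("<mcnet_dataset> %d observations x %d predictors; prevalence %.3f\n",
              nrow(x$X), ncol(x$X), mean(x$y)))
  invisible(x)
}

# Row-subset a dataset (used for CV folds); keeps metadata.
dataset_subset <- function(data, idx) {
  mc_dataset(data$X[idx, , drop = FALSE], data$y[idx],
             feature_names = data$feature_names,
             is_informative = data$is_informative)
}

#' Read a dataset from a delimited text file
#'
#' Reads a CSV with a header row; the column named by `outcome_col` becomes
#' the binary outcome and every other numeric column a predictor.
#'
#' @param path File path.
#' @param outcome_col Name of the outcome column.
#' @param sep Field separator, default comma.
#' @return An [mc_dataset()].
#' @export
read_dataset_csv <- function(path, outcome_col = "y", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!outcome_col %in% names(df)) {
    stop(sprintf("outcome column '%s' not found", outcome_col))
  }
  y <- df[[outcome_col]]
  df[[outcome_col]] <- NULL
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) {
    warning(sprintf("dropping %d non-numeric column(s)", sum(!num)))
    df <- df[num]
  }
  mc_dataset(as.matrix(df), y)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset_csv()]: predictors plus one outcome column.
#'
#' @param data An [mc_dataset()].
#' @param path File path.
#' @param outcome_col Name for the outcome column.
#' @export
write_dataset_csv <- function(data, path, outcome_col = "y") {
  df <- as.data.frame(data$X)
  df[[outcome_col]] <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
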