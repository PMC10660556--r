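#' Penalty configuration for the elastic-net solution path
#'
#' @param alpha Elastic-net mixing parameter in `[0, 1]`: `1` is the lasso,
#'   `0` pure ridge. The penalty is
#'   \eqn{\lambda \sum_j [\alpha |\beta_j| + (1-\alpha)\beta_j^2/2]}.
#' @param n_lambda Number of grid points on the descending \eqn{\lambda}
#'   path when no explicit grid is supplied.
#' @param lambda_min_ratio Ratio of the smallest to the largest grid
#'   \eqn{\lambda}. Default: `1e-2` when `p >= n` (high-dimensional case),
#'   else `1e-4`, matching the usual convention for binomial paths.
#' @param standardize Standardize predictors to unit variance internally
#'   before penalization (coefficients are always reported on the original
#'   scale).
#' @param thresh Convergence threshold passed to the coordinate-descent
#'   solver.
#' @param maxit Maximum number of passes over the data.
#' @return An object of class `mcnet_penalty`.
#' @export
penalty_config <- function(alpha = 1, n_lambda = 100L, lambda_min_ratio = NULL,
                           standardize = TRUE, thresh = 1e-7, maxit = 1e5) {
  stopifnot(alpha >= 0, alpha <= 1, n_lambda >= 2)
  if (!is.null(lambda_min_ratio)) {
    stopifnot(lambda_min_ratio > 0, lambda_min_ratio < 1)
  }
  structure(
    list(alpha = alpha, n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio, standardize = standardize,
         thresh = thresh, maxit = maxit),
    class = "mcnet_penalty"
  )
}

# Resolve the data-dependent default for lambda_min_ratio.
.lambda_min_ratio <- function(penalty, n, p) {
  if (!is.null(penalty$lambda_min_ratio)) return(penalty$lambda_min_ratio)
  if (n < p) 1e-2 else 1e-4
}

#' Fit the penalized logistic regression solution path
#'
#' Fits \eqn{\min_{\beta_0,\beta} -\frac{1}{n}\sum_i [y_i(\beta_0 + x_i^T\beta)
#' - \log(1 + e^{\beta_0 + x_i^T\beta})] + \lambda P_\alpha(\beta)} over a
#' descending \eqn{\lambda} grid, using the coordinate-descent solver of
#' \pkg{glmnet}. When `lambdas` is omitted the grid is data-derived:
#' \eqn{\lambda_{max}} is the smallest value at which all coefficients are
#' zero (from the KKT condition on standardized predictors), descending
#' log-spaced over `n_lambda` points down to
#' \eqn{\lambda_{max} \cdot} `lambda_min_ratio`.
#'
#' @param data An [mc_dataset()].
#' @param penalty A [penalty_config()].
#' @param lambdas Optional user grid; must be non-negative and strictly
#'   decreasing. A trailing zero is allowed (unpenalized fit).
#' @return An object of class `mcnet_path` with elements `lambdas`
#'   (descending grid), `a0` (per-lambda intercepts), `beta` (p x L sparse
#'   coefficient matrix on the original predictor scale), `df` (number of
#'   nonzero coefficients per lambda), `penalty`, and the training data
#'   (needed for exact off-grid refits).
#' @seealso [predict_prob()], [active_set()], [coef_at()]
#' @export
fit_path <- function(data, penalty = penalty_config(), lambdas = NULL) {
  stopifnot(inherits(data, "mcnet_dataset"))
  if (length(unique(data$y)) < 2L) stop("degenerate outcome")
  n <- nrow(data$X)
  p <- ncol(data$X)
  if (!is.null(lambdas)) {
    stopifnot(all(is.finite(lambdas)), all(lambdas >= 0))
    if (length(lambdas) > 1 && any(diff(lambdas) >= 0)) {
      stop("lambdas must be strictly decreasing")
    }
    fit <- glmnet::glmnet(
      data$X, data$y, family = "binomial", alpha = penalty$alpha,
      lambda = lambdas, standardize = penalty$standardize,
      thresh = penalty$thresh, maxit = penalty$maxit
    )
  } else {
    fit <- glmnet::glmnet(
      data$X, data$y, family = "binomial", alpha = penalty$alpha,
      nlambda = penalty$n_lambda,
      lambda.min.ratio = .lambda_min_ratio(penalty, n, p),
      standardize = penalty$standardize,
      thresh = penalty$thresh, maxit = penalty$maxit
    )
  }
  structure(
    list(lambdas = fit$lambda, a0 = as.numeric(fit$a0), beta = fit$beta,
         df = fit$df, penalty = penalty, feature_names = data$feature_names,
         X = data$X, y = data$y, glmnet_fit = fit),
    class = "mcnet_path"
  )
}

#' @export
print.mcnet_path <- function(x, ...) {
  cat(sprintf(
    "<mcnet_path> alpha=%g, %d lambdas in [%.4g, %.4g], p=%d, n=%d\n",
    x$penalty$alpha, length(x$lambdas), min(x$lambdas), max(x$lambdas),
    nrow(x$beta), length(x$y)))
  invisible(x)
}

# Locate `lambda` on the grid; returns the column index or NA if off-grid.
.grid_match <- function(path, lambda, rtol = 1e-9) {
  i <- which(abs(path$lambdas - lambda) <= rtol * pmax(path$lambdas, lambda))
  if (length(i)) i[1] else NA_integer_
}

#' Coefficients at an arbitrary penalty value
#'
#' Returns the intercept and coefficient vector of the path at `lambda`.
#' Grid values are read off the stored path; an off-grid `lambda` (e.g. the
#' median of cross-validation optima) triggers a fresh warm-started fit at
#' exactly that value — coefficients are never interpolated, because linear
#' interpolation does not preserve the sparsity pattern that defines the
#' signature.
#'
#' @param path An `mcnet_path`.
#' @param lambda Penalty value (non-negative).
#' @return List with `a0` (intercept) and `beta` (numeric vector, length p).
#' @export
coef_at <- function(path, lambda) {
  stopifnot(inherits(path, "mcnet_path"), length(lambda) == 1L, lambda >= 0)
  i <- .grid_match(path, lambda)
  if (!is.na(i)) {
    return(list(a0 = path$a0[i], beta = as.numeric(path$beta[, i])))
  }
  # warm-started refit: descend the stored grid to the target value
  lam2 <- c(path$lambdas[path$lambdas > lambda], lambda)
  pen <- path$penalty
  fit <- glmnet::glmnet(
    path$X, path$y, family = "binomial", alpha = pen$alpha, lambda = lam2,
    standardize = pen$standardize, thresh = pen$thresh, maxit = pen$maxit
  )
  j <- length(fit$lambda)
  list(a0 = as.numeric(fit$a0[j]), beta = as.numeric(fit$beta[, j]))
}

#' Predicted event probabilities
#'
#' Evaluates \eqn{\hat P(Y=1\mid x) = \mathrm{expit}(\hat\beta_0 +
#' x^T\hat\beta)} at the model for the requested penalty value.
#'
#' @param path An `mcnet_path`.
#' @param lambda Penalty value; off-grid values are refit exactly (see
#'   [coef_at()]).
#' @param X_new Numeric matrix of new observations (columns must match the
#'   training predictors).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(path, lambda, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(path$beta)) {
    stop(sprintf("X_new has %d columns; model expects %d",
                 ncol(X_new), nrow(path$beta)))
  }
  cf <- coef_at(path, lambda)
  stats::plogis(cf$a0 + as.numeric(X_new %*% cf$beta))
}

#' Active set (signature) at a penalty value
#'
#' Indices of predictors with nonzero coefficients at `lambda`; the
#' signature is this set and the signature size its cardinality. The
#' intercept is never counted.
#'
#' @inheritParams predict_prob
#' @return Integer vector of predictor indices (named by feature).
#' @export
active_set <- function(path, lambda) {
  cf <- coef_at(path, lambda)
  idx <- which(cf$beta != 0)
  names(idx) <- path$feature_names[idx]
  idx
}

#' Elastic-net penalized negative log-likelihood
#'
#' The objective minimized by [fit_path()], evaluated at an arbitrary
#' `(a0, beta)`: average negative Bernoulli log-likelihood plus
#' \eqn{\lambda[\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2/2]}. The penalty
#' applies to coefficients on the scale of `X` as given, so for comparison
#' against solver output use `standardize = FALSE` fits (or pre-scaled
#' predictors).
#'
#' @param X,y Data (matrix, 0/1 vector).
#' @param a0 Intercept.
#' @param beta Coefficient vector.
#' @param lambda,alpha Penalty strength and mixing.
#' @return Objective value (scalar).
#' @export
enet_objective <- function(X, y, a0, beta, lambda, alpha = 1) {
  eta <- a0 + as.numeric(X %*% beta)
  nll <- -mean(y * eta - log1pexp(eta))
  nll + lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Export a fitted model as JSON
#'
#' Writes `lambda`, the intercept and the named nonzero coefficients, i.e.
#' everything needed to score new data with the selected signature.
#'
#' @param object An `mcnet_mc` selection (preferred) or an `mcnet_path`.
#' @param path Output file path.
#' @param lambda Penalty value (required for `mcnet_path` input).
#' @export
write_model_json <- function(object, path, lambda = NULL) {
  if (inherits(object, "mcnet_mc")) {
    lambda <- object$lambda_final
    a0 <- object$final_fit$a0
    beta <- object$final_fit$beta
    nm <- object$feature_names
  } else if (inherits(object, "mcnet_path")) {
    stopifnot(!is.null(lambda))
    cf <- coef_at(object, lambda)
    a0 <- cf$a0
    beta <- cf$beta
    nm <- object$feature_names
  } else {
    stop("object must be an mcnet_mc or mcnet_path")
  }
  nz <- which(beta != 0)
  out <- list(lambda = lambda, intercept = a0,
              coefficients = as.list(stats::setNames(beta[nz], nm[nz])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
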