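# Small logistic-model fixtures built in code.

toy_data <- function(n, p, beta = NULL, seed = 1, intercept = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- rep(0, p)
  y <- rbinom(n, 1, plogis(intercept + X %*% beta))
  # guard against a degenerate draw on tiny fixtures
  if (length(unique(y)) < 2) {
    y[1] <- 0L
    y[2] <- 1L
  }
  mc_dataset(X, y)
}

# Pure-noise outcome: y independent of X.
null_data <- function(n, p, seed = 1) {
  set.seed(seed)
  mc_dataset(matrix(rnorm(n * p), n, p), rbinom(n, 1, 0.5))
}
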