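# Independent oracle for the penalized objective: direct numerical
# minimization of the elastic-net penalized negative log-likelihood with a
# smoothed absolute value (|x| ~ sqrt(x^2 + eps^2), eps tiny), multi-start
# BFGS. Used to certify that the path solver attains the convex optimum.

oracle_enet <- function(X, y, lambda, alpha = 1, eps = 1e-9, n_starts = 3,
                        seed = 1) {
  n <- nrow(X)
  p <- ncol(X)
  sobj <- function(par) {
    a0 <- par[1]
    b <- par[-1]
    eta <- a0 + as.numeric(X %*% b)
    nll <- -mean(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    nll + lambda * (alpha * sum(sqrt(b^2 + eps^2)) +
                    (1 - alpha) / 2 * sum(b^2))
  }
  sgrad <- function(par) {
    a0 <- par[1]
    b <- par[-1]
    eta <- a0 + as.numeric(X %*% b)
    r <- plogis(eta) - y
    c(mean(r),
      as.numeric(crossprod(X, r)) / n +
        lambda * (alpha * b / sqrt(b^2 + eps^2) + (1 - alpha) * b))
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- if (i == 1) rep(0, p + 1) else rnorm(p + 1, sd = 0.3)
    fit <- optim(start, sobj, sgrad, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(a0 = best$par[1], beta = best$par[-1],
       objective = enet_objective(X, y, best$par[1], best$par[-1],
                                  lambda, alpha))
}
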