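test_that("at the top of a data-derived lasso grid all coefficients are zero", {
  d <- toy_data(80, 8, beta = c(1, -0.5, rep(0, 6)), seed = 3)
  path <- fit_path(d, penalty_config(alpha = 1))
  expect_identical(unname(path$df[1]), 0L)
  expect_equal(as.numeric(path$beta[, 1]), rep(0, 8))
  # penalty dominates: intercept is the marginal log-odds
  expect_equal(path$a0[1], qlogis(mean(d$y)), tolerance = 1e-6)
  expect_identical(length(active_set(path, max(path$lambdas))), 0L)
})

test_that("an unpenalized fit recovers the logistic MLE", {
  d <- toy_data(50, 3, beta = c(0.8, -0.4, 0.2), seed = 7)
  # descend a path ending exactly at zero penalty
  lam <- c(exp(seq(log(0.3), log(1e-4), length.out = 30)), 0)
  path <- fit_path(d, penalty_config(alpha = 1, thresh = 1e-12), lambdas = lam)
  cf <- coef_at(path, 0)
  mle <- glm(d$y ~ d$X, family = binomial)
  expect_equal(cf$a0, unname(coef(mle)[1]), tolerance = 1e-4)
  expect_equal(cf$beta, unname(coef(mle)[-1]), tolerance = 1e-4)
})

test_that("path solutions attain the convex optimum (oracle comparison)", {
  d <- toy_data(30, 5, beta = c(1, -1, 0.5, 0, 0), seed = 11)
  pen <- penalty_config(alpha = 1, standardize = FALSE, thresh = 1e-12)
  path <- fit_path(d, pen)
  for (lam in c(0.1, 0.03, 0.01)) {
    cf <- coef_at(path, lam)
    ours <- enet_objective(d$X, d$y, cf$a0, cf$beta, lam, alpha = 1)
    orc <- oracle_enet(d$X, d$y, lam, alpha = 1)
    expect_lte(ours, orc$objective + 1e-6)
  }
  # elastic-net mixing too
  pen2 <- penalty_config(alpha = 0.5, standardize = FALSE, thresh = 1e-12)
  path2 <- fit_path(d, pen2)
  cf2 <- coef_at(path2, 0.05)
  expect_lte(enet_objective(d$X, d$y, cf2$a0, cf2$beta, 0.05, alpha = 0.5),
             oracle_enet(d$X, d$y, 0.05, alpha = 0.5)$objective + 1e-6)
})

test_that("the objective at any path solution beats the null model", {
  d <- toy_data(60, 10, beta = c(rep(0.6, 3), rep(0, 7)), seed = 5)
  pen <- penalty_config(alpha = 1, standardize = FALSE)
  path <- fit_path(d, pen)
  null_obj <- enet_objective(d$X, d$y, qlogis(mean(d$y)), rep(0, 10), 0)
  for (i in seq_along(path$lambdas)) {
    obj <- enet_objective(d$X, d$y, path$a0[i], as.numeric(path$beta[, i]),
                          path$lambdas[i], alpha = 1)
    null_i <- null_obj  # null model has zero penalty at any lambda
    expect_lte(obj, null_i + 1e-8)
  }
})

test_that("refitting at a grid lambda reproduces the path solution", {
  d <- toy_data(70, 6, beta = c(1, -0.7, 0.5, 0, 0, 0), seed = 13)
  path <- fit_path(d, penalty_config())
  for (i in c(10, 25, 40)) {
    lam <- path$lambdas[i]
    # force the refit branch by nudging lambda off the stored grid
    cf_refit <- coef_at(path, lam * (1 + 1e-7))
    expect_equal(cf_refit$beta, as.numeric(path$beta[, i]), tolerance = 1e-5)
    expect_equal(cf_refit$a0, path$a0[i], tolerance = 1e-5)
  }
})

test_that("predicted probabilities follow the linear predictor exactly", {
  d <- toy_data(40, 4, beta = c(1, 0, 0, 0), seed = 17)
  path <- fit_path(d, penalty_config())
  lam <- path$lambdas[15]
  cf <- coef_at(path, lam)
  x_row <- matrix(c(0.3, -1.2, 0.5, 2), 1)
  expect_equal(predict_prob(path, lam, x_row),
               plogis(cf$a0 + sum(x_row * cf$beta)))
  # all-zero model at the grid top with balanced classes: probs ~ expit(a0)
  p_top <- predict_prob(path, max(path$lambdas), x_row)
  expect_equal(p_top, plogis(qlogis(mean(d$y))), tolerance = 1e-6)
  expect_true(all(p_top > 0 & p_top < 1))
})

test_that("active set grows to all predictors as the penalty vanishes", {
  d <- toy_data(200, 4, beta = c(1, -0.8, 0.6, 0.4), seed = 19)
  lam <- c(exp(seq(log(0.5), log(1e-6), length.out = 40)))
  path <- fit_path(d, penalty_config(), lambdas = lam)
  expect_identical(sort(unname(active_set(path, 1e-6))), 1:4)
})

test_that("a dominant predictor is selected alone at moderate penalty", {
  set.seed(23)
  X <- matrix(rnorm(300 * 5), 300, 5)
  y <- rbinom(300, 1, plogis(2.5 * X[, 1]))
  d <- mc_dataset(X, y)
  path <- fit_path(d, penalty_config())
  # the strong predictor is the first to enter the path
  first_active <- which(path$df >= 1)[1]
  act <- active_set(path, path$lambdas[first_active])
  expect_identical(unname(act), 1L)
})

test_that("degenerate and malformed inputs are rejected", {
  expect_error(mc_dataset(matrix(rnorm(20), 10, 2), rep(1, 10)),
               "single class")
  X <- matrix(rnorm(20), 10, 2)
  X[3, 1] <- NA
  expect_error(mc_dataset(X, rep(0:1, 5)), "non-finite")
  d <- toy_data(30, 3, seed = 29)
  path <- fit_path(d, penalty_config())
  expect_error(predict_prob(path, path$lambdas[5], matrix(0, 2, 7)),
               "columns")
  expect_error(fit_path(d, penalty_config(),
                        lambdas = c(0.1, 0.2)),  # increasing
               "decreasing")
})

test_that("model JSON export round-trips the nonzero coefficients", {
  d <- toy_data(60, 5, beta = c(1.5, -1, 0, 0, 0), seed = 31)
  sel <- mc_select(d, penalty_config(n_lambda = 30), s = 2, k = 5, seed = 1)
  f <- tempfile(fileext = ".json")
  write_model_json(sel, f)
  m <- jsonlite::read_json(f)
  expect_equal(m$lambda, sel$lambda_final)
  expect_equal(m$intercept, sel$final_fit$a0)
  expect_setequal(names(m$coefficients), names(sel$signature))
  unlink(f)
})

test_that("CSV dataset round trip preserves data and outcome", {
  d <- toy_data(25, 3, seed = 37)
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(d, f, outcome_col = "outcome")
  d2 <- read_dataset_csv(f, outcome_col = "outcome")
  expect_equal(unname(d2$X), unname(d$X), tolerance = 1e-12)
  expect_identical(d2$y, d$y)
  unlink(f)
})
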