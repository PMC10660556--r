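# Calibration constant for the generator's linear predictor. The canonical
# signal levels m = 0.04 / 0.07 / 0.15 with base coefficients (8,7,6,5,4)
# are defined to operate at generative AUC ~ 0.70 / 0.80 / 0.92; hitting
# those operating points requires scaling the linear predictor by sqrt(2)
# relative to the bare coefficient products (verified by quadrature on the
# induced case/control score distributions).
.signal_scale <- sqrt(2)

# Effective generating coefficients for signal level m.
.true_beta <- function(m) .signal_scale * m * c(8, 7, 6, 5, 4)

#' Scenario configuration for the synthetic study generator
#'
#' Describes one simulation scenario: five informative standard-normal
#' predictors with logistic-model coefficients proportional to
#' `(8, 7, 6, 5, 4) * m` (intercept 0, so classes are balanced on average),
#' `m1` independent standard-normal noise predictors, and `m2` correlated
#' surrogate predictors, half at correlation 0.5 and half at 0.8 with the
#' informative ones.
#'
#' Surrogate parentage is fixed: parents cycle over X1..X5 (only X1 and X2
#' when `m2 = 4`), each parent receiving `m2 / n_parents` surrogates, the
#' first half at the lower correlation and the second half at the higher
#' one. So for `m2 = 400`, 80 surrogates track each informative predictor,
#' 40 at 0.5 and 40 at 0.8.
#'
#' @param m Signal level; canonical values 0.04, 0.07, 0.15 (generative AUC
#'   approximately 0.70, 0.80, 0.92).
#' @param n_train Training set size.
#' @param m1 Number of independent noise predictors.
#' @param m2 Number of correlated surrogate predictors (even; canonical 4,
#'   40, 400).
#' @param n_test Test set size (default 10000 — large, so the test AUC is an
#'   effectively external measure of the fitted model).
#' @param rho_levels Two correlation levels for the surrogates.
#' @param seed Seed for dataset generation.
#' @return Object of class `mcnet_scenario`.
#' @export
scenario_config <- function(m, n_train, m1, m2, n_test = 10000L,
                            rho_levels = c(0.5, 0.8), seed = 1L) {
  stopifnot(m >= 0, n_train >= 10, m1 >= 0, m2 >= 0,
            length(rho_levels) == 2L)
  if (m2 > 0) {
    if (m2 %% 2 != 0) stop("m2 must be even")
    n_par <- if (m2 %% 10 == 0) 5L else 2L
    if (m2 %% (2L * n_par) != 0) {
      stop("m2 must split evenly over parents and correlation levels")
    }
  }
  structure(
    list(m = m, n_train = as.integer(n_train), m1 = as.integer(m1),
         m2 = as.integer(m2), n_test = as.integer(n_test),
         rho_levels = sort(rho_levels), seed = as.integer(seed)),
    class = "mcnet_scenario"
  )
}

# Surrogate layout: data.frame of (parent, rho) per correlated column.
.surrogate_layout <- function(cfg) {
  m2 <- cfg$m2
  if (m2 == 0) return(data.frame(parent = integer(0), rho = numeric(0)))
  n_par <- if (m2 %% 10 == 0) 5L else 2L
  per <- m2 %/% n_par
  j <- seq_len(m2) - 1L
  data.frame(
    parent = j %/% per + 1L,
    rho = ifelse(j %% per < per / 2, cfg$rho_levels[1], cfg$rho_levels[2])
  )
}

# One draw of (X, y, true linear predictor) with n rows under cfg.
.simulate_block <- function(cfg, n) {
  p <- 5L + cfg$m1 + cfg$m2
  X <- matrix(0, n, p)
  X[, 1:5] <- stats::rnorm(n * 5L)
  b <- .true_beta(cfg$m)
  lp <- as.numeric(X[, 1:5] %*% b)
  y <- stats::rbinom(n, 1L, stats::plogis(lp))
  if (cfg$m1 > 0) {
    X[, 5L + seq_len(cfg$m1)] <- stats::rnorm(n * cfg$m1)
  }
  if (cfg$m2 > 0) {
    lay <- .surrogate_layout(cfg)
    Z <- matrix(stats::rnorm(n * cfg$m2), n, cfg$m2)
    X[, 5L + cfg$m1 + seq_len(cfg$m2)] <-
      X[, lay$parent, drop = FALSE] %*% diag(lay$rho, cfg$m2) +
      Z %*% diag(sqrt(1 - lay$rho^2), cfg$m2)
  }
  list(X = X, y = y, lp = lp)
}

#' Generate one training/test pair under a scenario
#'
#' Draws a training set of `n_train` observations and an independent test
#' set of `n_test` observations from the same generating model, together
#' with the generating coefficient vector and the true event probabilities
#' (the latter enable computing the external AUC ceiling of any fitted
#' model).
#'
#' @param cfg A [scenario_config()].
#' @return Object of class `mcnet_sim`: `train` and `test`
#'   ([mc_dataset()]s with informativeness flags), `truth` (length-p
#'   generating coefficients), `true_prob_train`, `true_prob_test`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "mcnet_scenario"))
  lay <- .surrogate_layout(cfg)
  nm <- c(paste0("X", 1:5),
          if (cfg$m1 > 0) paste0("N", seq_len(cfg$m1)),
          if (cfg$m2 > 0) sprintf("C%d_X%d_r%02d", seq_len(cfg$m2),
                                  lay$parent, round(100 * lay$rho)))
  p <- 5L + cfg$m1 + cfg$m2
  info <- c(rep(TRUE, 5), rep(FALSE, p - 5L))
  out <- with_seed(cfg$seed, {
    tr <- .simulate_block(cfg, cfg$n_train)
    te <- .simulate_block(cfg, cfg$n_test)
    list(tr = tr, te = te)
  })
  truth <- c(.true_beta(cfg$m), rep(0, p - 5L))
  names(truth) <- nm
  structure(
    list(train = mc_dataset(out$tr$X, out$tr$y, feature_names = nm,
                            is_informative = info),
         test = mc_dataset(out$te$X, out$te$y, feature_names = nm,
                           is_informative = info),
         truth = truth,
         true_prob_train = stats::plogis(out$tr$lp),
         true_prob_test = stats::plogis(out$te$lp),
         config = cfg),
    class = "mcnet_sim"
  )
}

#' Generative (true-model) AUC at a signal level
#'
#' Monte Carlo estimate of the AUC of the true event probability against
#' outcomes simulated from it — the performance ceiling any fitted model
#' can approach under the scenario's generating model.
#'
#' @param m Signal level (or a [scenario_config()], whose `m` is used).
#' @param n_mc Monte Carlo sample size.
#' @param seed Seed.
#' @return AUC estimate.
#' @export
true_auc <- function(m, n_mc = 2e5, seed = 1L) {
  if (inherits(m, "mcnet_scenario")) m <- m$m
  stopifnot(m >= 0)
  b <- .true_beta(m)
  with_seed(seed, {
    # b.X with X ~ iid N(0,1) is exactly N(0, ||b||^2); simulate the score
    lp <- stats::rnorm(n_mc, 0, sqrt(sum(b^2)))
    pr <- stats::plogis(lp)
    y <- stats::rbinom(n_mc, 1L, pr)
    auc(pr, y)
  })
}

#' External AUC of a fitted model on a test set
#'
#' Scores the test set with the model's linear predictor and returns the
#' AUC against the test outcomes.
#'
#' @param object An `mcnet_mc` selection, or an `mcnet_path` with `lambda`.
#' @param test An [mc_dataset()] test set.
#' @param lambda Penalty value (only for `mcnet_path` input).
#' @return AUC on the test set.
#' @export
external_auc <- function(object, test, lambda = NULL) {
  stopifnot(inherits(test, "mcnet_dataset"))
  if (inherits(object, "mcnet_mc")) {
    a0 <- object$final_fit$a0
    beta <- object$final_fit$beta
  } else if (inherits(object, "mcnet_path")) {
    stopifnot(!is.null(lambda))
    cf <- coef_at(object, lambda)
    a0 <- cf$a0
    beta <- cf$beta
  } else {
    stop("object must be an mcnet_mc or mcnet_path")
  }
  auc(a0 + as.numeric(test$X %*% beta), test$y)
}

#' The 27 canonical study scenarios
#'
#' Full crossing of three signal levels (m = 0.04, 0.07, 0.15), three
#' training sizes (100, 500, 1000) and three noise dimensions (m1 = 50,
#' 500, 5000 paired with m2 = 4, 40, 400 surrogates). Row order: signal
#' outermost, then training size, then noise dimension — scenario 1 is the
#' weak-signal, n=100, 50-noise case.
#'
#' @return Data frame with columns `scenario`, `m`, `n_train`, `m1`, `m2`.
#' @export
scenario_table <- function() {
  grid <- expand.grid(m1 = c(50L, 500L, 5000L),
                      n_train = c(100L, 500L, 1000L),
                      m = c(0.04, 0.07, 0.15))
  grid$m2 <- c(4L, 40L, 400L)[match(grid$m1, c(50L, 500L, 5000L))]
  data.frame(scenario = seq_len(nrow(grid)),
             m = grid$m, n_train = grid$n_train,
             m1 = grid$m1, m2 = grid$m2)
}

#' Scenario configuration by study scenario number
#'
#' @param id Scenario number, 1..27 (see [scenario_table()]).
#' @param seed Seed for generation.
#' @param ... Further arguments passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
scenario_config_by_id <- function(id, seed = 1L, ...) {
  tab <- scenario_table()
  stopifnot(id %in% tab$scenario)
  row <- tab[tab$scenario == id, ]
  scenario_config(m = row$m, n_train = row$n_train, m1 = row$m1,
                  m2 = row$m2, seed = seed, ...)
}
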