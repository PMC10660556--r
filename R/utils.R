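# Internal helpers: RNG hygiene and numerics.

# Save/restore the global RNG state so that functions taking an explicit
# `seed` argument do not perturb the caller's random number stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible child seeds from a master seed
#'
#' A master seed spawns `n` child seeds through a fixed mixing scheme, so
#' that repeated cross-validation runs (and outer-wrapper repeats) are
#' reproducible and independent of evaluation order. All derived seeds are
#' strictly below 2^31.
#'
#' @param seed Master seed (single integer).
#' @param n Number of child seeds.
#' @param salt Integer stream identifier separating independent uses of the
#'   same master seed (e.g. the Monte Carlo stream vs. the outer-CV stream).
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), n >= 1)
  mix <- (abs(as.double(seed)) * 48271 + as.double(salt) * 16807 + 1) %% 2147483587
  with_seed(as.integer(mix), sample.int(2147483399L, n, replace = FALSE))
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out
}
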