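# Internal numerical helpers shared across estimation routes.

#' @importFrom stats rnorm dnorm pnorm qnorm integrate cov
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw multivariate normal deviates via a lower-triangular factor
#'
#' Draws use the lower Cholesky factor of the covariance, so a fixed RNG
#' state yields a fixed sample. Row-per-draw matrix is returned.
#'
#' @param m number of draws
#' @param mu mean vector
#' @param L lower-triangular factor with `L %*% t(L) == Sigma`
#' @return an `m x n` matrix of draws
#' @noRd
rmvn_chol <- function(m, mu, L) {
  n <- length(mu)
  z <- matrix(stats::rnorm(m * n), nrow = n, ncol = m)
  t(L %*% z + mu)
}

# Lower Cholesky factor with the positive-definiteness error of the
# parameter constructor; `what` names the offending matrix in messages.
chol_lower <- function(sigma, what = "Sigma") {
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop(sprintf("%s is not positive definite (Cholesky factorisation failed)",
                 what), call. = FALSE)
  })
  t(ch)
}

# Evaluate `expr` under a deterministic seed without disturbing the
# caller's RNG stream. Used to make randomised-QMC backends repeatable.
with_fixed_seed <- function(seed, expr) {
  withr::with_preserve_seed({
    set.seed(seed)
    force(expr)
  })
}

# Derive a child seed (< 2^31) from a master seed and a stream label.
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483587) + 1L
}

# Multivariate normal density at rows of x (no dependency on the
# sampling path; used by the quadrature oracle and marginal densities).
dmvn <- function(x, mu, sigma, log = FALSE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- length(mu)
  L <- chol_lower(sigma)
  z <- forwardsolve(L, t(x) - mu)
  logdet <- 2 * sum(log(diag(L)))
  ld <- -0.5 * colSums(z^2) - 0.5 * (n * log(2 * pi) + logdet)
  if (log) ld else exp(ld)
}
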