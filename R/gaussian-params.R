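#' Parameters of the untruncated multivariate normal distribution
#'
#' Bundles the mean vector and covariance matrix of the *untruncated*
#' multivariate normal (MND) whose restriction to the non-negative region
#' under the unit simplex (`x_i >= 0` for all `i`, `sum(x) <= 1`) defines
#' the simplex-truncated MND (ST-MND). The covariance is symmetrised as
#' `(Sigma + t(Sigma)) / 2` after a relative symmetry check, and strict
#' positive definiteness is required: the smallest eigenvalue must exceed
#' `pd_floor * trace(Sigma)`. A positive-semi-definite matrix with a zero
#' eigenvalue is rejected, since every estimation route needs either a
#' factorisation of Sigma or the inverse of a transformed covariance.
#'
#' @param mu numeric mean vector of length `n`.
#' @param sigma numeric `n x n` covariance matrix.
#' @param sym_tol relative tolerance for the symmetry check (default `1e-10`).
#' @param pd_floor smallest admissible eigenvalue, as a fraction of the
#'   trace (default `1e-12`).
#' @return an object of class `gaussian_params` with elements `n`, `mu`,
#'   `sigma` and the cached lower-triangular factor `L`.
#' @examples
#' p <- gaussian_params(c(0.45, 0.28), matrix(c(0.17, 0.04, 0.04, 0.06), 2))
#' p$n
#' @export
gaussian_params <- function(mu, sigma, sym_tol = 1e-10, pd_floor = 1e-12) {
  mu <- as.numeric(mu)
  n <- length(mu)
  if (n < 1) stop("mu must have length >= 1", call. = FALSE)
  sigma <- as.matrix(sigma)
  if (!is.numeric(sigma) || nrow(sigma) != n || ncol(sigma) != n) {
    stop(sprintf("sigma must be a numeric %d x %d matrix", n, n), call. = FALSE)
  }
  if (anyNA(mu) || anyNA(sigma)) stop("mu and sigma must be finite", call. = FALSE)
  asym <- max(abs(sigma - t(sigma)))
  scale <- max(abs(sigma), 1e-300)
  if (asym > sym_tol * scale) {
    stop(sprintf("sigma is not symmetric (max |sigma - t(sigma)| = %.3e)", asym),
         call. = FALSE)
  }
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= pd_floor * sum(diag(sigma))) {
    stop(sprintf(paste0("sigma is not strictly positive definite ",
                        "(smallest eigenvalue %.3e <= %.3e); ",
                        "add a small diagonal jitter if the matrix is ",
                        "semi-definite by construction"),
                 min(ev), pd_floor * sum(diag(sigma))), call. = FALSE)
  }
  structure(
    list(n = n, mu = mu, sigma = sigma, L = chol_lower(sigma)),
    class = "gaussian_params"
  )
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat(sprintf("<gaussian_params> n = %d\n", x$n))
  cat("mu:   ", paste(signif(x$mu, 5), collapse = ", "), "\n")
  cat("sigma:\n")
  print(signif(x$sigma, 5))
  invisible(x)
}

is_gaussian_params <- function(x) inherits(x, "gaussian_params")

#' Linear constraint system of the (loosened) simplex domain
#'
#' Expresses the ST-MND domain in centred coordinates `y = x - mu` as the
#' linear system `A y + c' >= 0` with `n + 1` rows: the first row of `A`
#' is `-1` in every entry (the `sum(x) <= 1` face) and the remaining rows
#' are the identity (the `x_i >= 0` faces); `c = (1 - sum(mu), mu)`. A
#' non-negative loosening shift `gamma` relaxes every constraint uniformly,
#' `c' = c + gamma`, producing the nested domains used by subset simulation;
#' `gamma = 0` recovers the exact simplex domain.
#'
#' @param params a [gaussian_params()] object.
#' @param gamma non-negative loosening shift (default 0).
#' @return an object of class `simplex_domain` with elements `A`, `c`,
#'   `c_prime` and `gamma`.
#' @examples
#' d <- simplex_domain(gaussian_params(c(0.3, 0.2), diag(0.01, 2)))
#' d$A
#' d$c
#' @export
simplex_domain <- function(params, gamma = 0) {
  stopifnot(is_gaussian_params(params))
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) || gamma < 0) {
    stop("gamma must be a single non-negative number", call. = FALSE)
  }
  n <- params$n
  A <- rbind(rep(-1, n), diag(n))
  cc <- c(1 - sum(params$mu), params$mu)
  structure(
    list(A = A, c = cc, c_prime = cc + gamma, gamma = gamma),
    class = "simplex_domain"
  )
}

#' Membership test for the (loosened) simplex domain
#'
#' Tests whether a point `x` (in original coordinates) lies in the simplex
#' domain loosened by `gamma`, i.e. whether `A (x - mu) + c + gamma >= 0`
#' elementwise. For `gamma = 0` this is exactly `all(x >= 0)` together with
#' `sum(x) <= 1`. Boundary points count as inside.
#'
#' @param x numeric vector of length `n`, or a matrix with one point per row.
#' @param params a [gaussian_params()] object.
#' @param gamma non-negative loosening shift (default 0).
#' @return logical scalar (or vector, for matrix input).
#' @examples
#' p <- gaussian_params(c(0.3, 0.2), diag(0.01, 2))
#' in_domain(c(0.2, 0.3), p)
#' in_domain(c(0.6, 0.6), p)
#' @export
in_domain <- function(x, params, gamma = 0) {
  stopifnot(is_gaussian_params(params))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != params$n) {
    stop(sprintf("x has %d columns but the distribution has dimension %d",
                 ncol(x), params$n), call. = FALSE)
  }
  rs <- rowSums(x)
  apply(x >= -gamma, 1, all) & (rs <= 1 + gamma)
}
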