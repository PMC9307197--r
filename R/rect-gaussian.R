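#' Zero-mean Gaussian with hyperrectangular truncation
#'
#' Container for a zero-mean multivariate normal with covariance `eps`
#' restricted to the box `a < w < b`, where bound entries may be infinite.
#' These objects arise from [transform_to_rect()]: any Gaussian truncated
#' by at most `n` linear constraints of full rank can be rewritten in this
#' form, after which its probability mass and first two moments follow
#' from rectangle probabilities alone.
#'
#' @param eps `n x n` symmetric positive-definite covariance.
#' @param a,b lower/upper bounds (entries may be `-Inf` / `Inf`), `a < b`
#'   componentwise.
#' @return an object of class `rect_gaussian`.
#' @export
rect_gaussian <- function(eps, a, b) {
  eps <- as.matrix(eps)
  a <- as.numeric(a)
  b <- as.numeric(b)
  n <- nrow(eps)
  stopifnot(ncol(eps) == n, length(a) == n, length(b) == n)
  if (any(a >= b)) stop("bounds must satisfy a < b componentwise", call. = FALSE)
  if (max(abs(eps - t(eps))) > 1e-10 * max(abs(eps))) {
    stop("eps must be symmetric", call. = FALSE)
  }
  eps <- (eps + t(eps)) / 2
  if (min(eigen(eps, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("eps must be positive definite", call. = FALSE)
  }
  structure(list(eps = eps, a = a, b = b, n = n), class = "rect_gaussian")
}

#' Rectangle probability of a multivariate normal
#'
#' Computes `Phi(a, b; mu, Sigma)`, the probability that `N(mu, Sigma)`
#' falls in the box `a <= x <= b`. Dimensions 1 and 2-or-more delegate to
#' `stats::pnorm` and `mvtnorm::pmvnorm` (Genz-Bretz randomised
#' quasi-Monte-Carlo) respectively; the quasi-Monte-Carlo call runs under
#' a fixed internal seed, with the caller's RNG stream preserved, so
#' repeated evaluations are identical. The result is clipped to `[0, 1]`.
#'
#' @param a,b bound vectors (entries may be infinite).
#' @param mu mean vector.
#' @param Sigma covariance matrix.
#' @param abs_tol requested absolute accuracy (default `1e-6`).
#' @param maxpts evaluation budget passed to the backend.
#' @return scalar probability.
#' @examples
#' rect_integral(c(0, 0), c(Inf, Inf), c(0, 0),
#'               matrix(c(1, 0.5, 0.5, 1), 2))  # orthant prob, 1/3
#' @export
rect_integral <- function(a, b, mu, Sigma, abs_tol = 1e-6, maxpts = 100000L) {
  a <- as.numeric(a); b <- as.numeric(b); mu <- as.numeric(mu)
  if (any(a >= b)) stop("bounds must satisfy a < b componentwise", call. = FALSE)
  n <- length(mu)
  if (n == 1) {
    s <- sqrt(as.numeric(Sigma))
    p <- stats::pnorm((b - mu) / s) - stats::pnorm((a - mu) / s)
    return(min(max(p, 0), 1))
  }
  res <- with_fixed_seed(20220722L, tryCatch(
    mvtnorm::pmvnorm(lower = a, upper = b, mean = mu, sigma = as.matrix(Sigma),
                     algorithm = mvtnorm::GenzBretz(abseps = abs_tol,
                                                    releps = 0,
                                                    maxpts = maxpts)),
    error = function(e) e))
  if (inherits(res, "error")) {
    stop(sprintf("rectangle-probability backend failed (%s) for a = [%s], b = [%s]",
                 conditionMessage(res),
                 paste(signif(a, 4), collapse = ", "),
                 paste(signif(b, 4), collapse = ", ")), call. = FALSE)
  }
  min(max(as.numeric(res), 0), 1)
}

#' Transform a linearly constrained Gaussian to a rectangular one
#'
#' Given a full-rank matrix `T` and bounds `c < T x < d` on
#' `x ~ N(mu, Sigma)`, the transformed variable `w = T (x - mu)` is a
#' zero-mean Gaussian with covariance `eps = T Sigma T'` restricted to the
#' box `a = c - T mu < w < b = d - T mu`. Infinite entries of `c`, `d`
#' propagate unchanged.
#'
#' @param T square full-rank transformation matrix.
#' @param c,d lower/upper constraint vectors (entries may be infinite).
#' @param params a [gaussian_params()] object.
#' @return a [rect_gaussian()] object.
#' @export
transform_to_rect <- function(T, c, d, params) {
  stopifnot(is_gaussian_params(params))
  T <- as.matrix(T)
  n <- params$n
  stopifnot(nrow(T) == n, ncol(T) == n, length(c) == n, length(d) == n)
  if (qr(T)$rank < n) stop("T must have full rank", call. = FALSE)
  Tmu <- as.numeric(T %*% params$mu)
  rect_gaussian(eps = T %*% params$sigma %*% t(T),
                a = c - Tmu, b = d - Tmu)
}

#' Total probability mass of a rectangularly truncated Gaussian
#'
#' `Phi(a, b; 0, eps)` for a [rect_gaussian()] object; callers that
#' evaluate several marginal densities cache this value and pass it as
#' `Z_rect`.
#'
#' @param rect a [rect_gaussian()] object.
#' @param abs_tol backend accuracy.
#' @return scalar probability.
#' @export
rect_mass <- function(rect, abs_tol = 1e-6) {
  rect_integral(rect$a, rect$b, rep(0, rect$n), rect$eps, abs_tol = abs_tol)
}

#' Univariate marginal density of a rectangularly truncated Gaussian
#'
#' Evaluates the `k`-th marginal density `F_k(w_k)` of the zero-mean
#' truncated Gaussian in `rect`: the unconditional normal density of
#' `W_k` at `w_k` times the `(n-1)`-dimensional rectangle probability of
#' the conditional distribution of the remaining coordinates (conditional
#' mean `w_k * eps[-k, k] / eps[k, k]`, conditional covariance the Schur
#' complement of `eps[k, k]`), normalised by the truncated mass. For
#' `n = 2` this reduces to a normal density times a univariate interval
#' probability over `|eps| / eps_kk`.
#'
#' @param k coordinate index.
#' @param w_k evaluation point (finite).
#' @param rect a [rect_gaussian()] object.
#' @param abs_tol backend accuracy for rectangle probabilities.
#' @param Z_rect optional precomputed total mass `Phi(a, b; 0, eps)`.
#' @return scalar density value.
#' @export
marginal_univariate <- function(k, w_k, rect, abs_tol = 1e-6, Z_rect = NULL) {
  stopifnot(inherits(rect, "rect_gaussian"), k >= 1, k <= rect$n)
  if (!is.finite(w_k)) stop("w_k must be finite", call. = FALSE)
  eps <- rect$eps
  n <- rect$n
  Z_rect <- Z_rect %||% rect_mass(rect, abs_tol)
  dens <- stats::dnorm(w_k, 0, sqrt(eps[k, k]))
  if (n == 1) return(dens / Z_rect)
  cm <- w_k * eps[-k, k] / eps[k, k]
  cv <- eps[-k, -k, drop = FALSE] -
    outer(eps[-k, k], eps[k, -k]) / eps[k, k]   # Schur complement
  cond <- rect_integral(rect$a[-k], rect$b[-k], cm, cv, abs_tol = abs_tol)
  dens * cond / Z_rect
}

# Correlation matrix of eps (unit diagonal).
cor_from_cov <- function(eps) {
  s <- sqrt(diag(eps))
  eps / outer(s, s)
}

# First-order partial correlation rho_ij.m for all i, j at fixed m.
# Row/column m of the result is meaningless (the conditioning variable
# cannot be partialled on itself) and is always dropped by callers; the
# self-correlation is zeroed first so no 0/0 arises there.
partial_cor1 <- function(rho, m) {
  # row/col m of rho may itself be discarded output of a previous pass
  # (values outside [-1, 1]); clamp so no NaN leaks from unused entries
  x <- pmin(pmax(rho[, m], -1), 1)
  x[m] <- 0
  num <- rho - outer(x, x)
  den <- sqrt(outer(1 - x^2, 1 - x^2))
  out <- num / den
  diag(out) <- 1
  out
}

#' Partial-correlation workspace for a conditioning pair
#'
#' Computes, from a covariance `eps`, the quantities needed by the
#' bivariate marginal density with conditioning pair `(k, q)`: the
#' correlation matrix, the first-order partial correlations given `q` and
#' given `k`, the partial regression coefficients of each coordinate on
#' `w_k` and `w_q`, and the second-order partial correlation matrix
#' `R_kq`. Degenerate (`|rho| = 1`) configurations raise an error.
#'
#' @param eps covariance matrix.
#' @param k,q distinct conditioning indices.
#' @return a list with `rho`, `beta_k` (coefficients on `w_k` given `q`),
#'   `beta_q`, `R_kq`, and the conditional standard deviations `csd`.
#' @export
partial_correlations <- function(eps, k, q) {
  stopifnot(k != q)
  rho <- cor_from_cov(eps)
  if (any(abs(rho[upper.tri(rho)]) >= 1 - 1e-12)) {
    stop("degenerate correlation (|rho| = 1) in partial-correlation formulae",
         call. = FALSE)
  }
  n <- nrow(eps)
  idx <- seq_len(n)
  # partial regression of z_i on z_k controlling q, and on z_q controlling k
  beta_k <- (rho[, k] - rho[, q] * rho[k, q]) / (1 - rho[k, q]^2)
  beta_q <- (rho[, q] - rho[, k] * rho[q, k]) / (1 - rho[q, k]^2)
  rho_g_k <- partial_cor1(rho, k)
  if (any(abs(rho_g_k[idx != k, q][idx[idx != k] != q]) >= 1 - 1e-12)) {
    stop("degenerate first-order partial correlation", call. = FALSE)
  }
  R_kq <- partial_cor1(rho_g_k, q)
  # conditional sd of z_i given z_k, z_q (recursive variance decomposition):
  # sqrt((1 - rho_iq^2) (1 - rho_ik.q^2))
  rho_g_q <- partial_cor1(rho, q)
  csd <- sqrt(pmax((1 - rho[, q]^2) * (1 - rho_g_q[, k]^2), 0))
  list(rho = rho, beta_k = beta_k, beta_q = beta_q, R_kq = R_kq, csd = csd)
}

#' Bivariate marginal density of a rectangularly truncated Gaussian
#'
#' Evaluates the `(k, q)`-th bivariate marginal density `F_kq(w_k, w_q)`:
#' the bivariate normal density under the `(k, q)` submatrix of `eps`,
#' times the `(n-2)`-dimensional rectangle probability of the remaining
#' coordinates under their second-order partial correlation matrix with
#' standardised conditional bounds, normalised by the truncated mass. For
#' `n = 2` the conditional factor is empty (a dimension-zero rectangle
#' probability, defined as 1) and the density reduces to
#' `dmvnorm(w; 0, eps) / Phi(a, b; 0, eps)`. The function is symmetric
#' under swapping `(k, w_k)` with `(q, w_q)`.
#'
#' @param k,q distinct coordinate indices.
#' @param w_k,w_q evaluation points (finite).
#' @param rect a [rect_gaussian()] object.
#' @param abs_tol backend accuracy for rectangle probabilities.
#' @param Z_rect optional precomputed total mass.
#' @return scalar density value.
#' @export
marginal_bivariate <- function(k, q, w_k, w_q, rect, abs_tol = 1e-6,
                               Z_rect = NULL) {
  stopifnot(inherits(rect, "rect_gaussian"), k != q)
  if (!is.finite(w_k) || !is.finite(w_q)) {
    stop("w_k and w_q must be finite", call. = FALSE)
  }
  eps <- rect$eps
  n <- rect$n
  Z_rect <- Z_rect %||% rect_mass(rect, abs_tol)
  eps_kq <- eps[c(k, q), c(k, q)]
  dens <- dmvn(c(w_k, w_q), c(0, 0), eps_kq)
  if (n == 2) return(dens / Z_rect)
  pc <- partial_correlations(eps, k, q)
  rest <- setdiff(seq_len(n), c(k, q))
  sd_all <- sqrt(diag(eps))
  cmean <- pc$beta_k * w_k / sd_all[k] + pc$beta_q * w_q / sd_all[q]
  a_star <- (rect$a / sd_all - cmean) / pc$csd
  b_star <- (rect$b / sd_all - cmean) / pc$csd
  Rm <- pc$R_kq[rest, rest, drop = FALSE]
  cond <- rect_integral(a_star[rest], b_star[rest], rep(0, length(rest)), Rm,
                        abs_tol = abs_tol)
  dens * cond / Z_rect
}

#' First raw moment of a rectangularly truncated zero-mean Gaussian
#'
#' Moment-generating-function identity:
#' `E(W_i) = sum_k eps_ik (F_k(a_k) - F_k(b_k))`, where marginal densities
#' evaluated at infinite endpoints are zero (Gaussian tails dominate).
#'
#' @param rect a [rect_gaussian()] object.
#' @param abs_tol backend accuracy.
#' @return length-`n` vector of first moments.
#' @export
first_moment <- function(rect, abs_tol = 1e-6) {
  eps <- rect$eps
  n <- rect$n
  Z_rect <- rect_mass(rect, abs_tol)
  Fa <- vapply(seq_len(n), function(k) {
    if (is.finite(rect$a[k]))
      marginal_univariate(k, rect$a[k], rect, abs_tol, Z_rect) else 0
  }, numeric(1))
  Fb <- vapply(seq_len(n), function(k) {
    if (is.finite(rect$b[k]))
      marginal_univariate(k, rect$b[k], rect, abs_tol, Z_rect) else 0
  }, numeric(1))
  as.numeric(eps %*% (Fa - Fb))
}

#' Second raw moment of a rectangularly truncated zero-mean Gaussian
#'
#' Moment-generating-function identity for `E(W_i W_j)`: the untruncated
#' covariance `eps_ij`, plus a single sum of endpoint-weighted univariate
#' marginal densities, plus a double sum over coordinate pairs of the
#' four-corner combination of bivariate marginal densities. Terms with an
#' infinite endpoint vanish. The result is symmetrised.
#'
#' @param rect a [rect_gaussian()] object.
#' @param abs_tol backend accuracy.
#' @return `n x n` matrix of second raw moments.
#' @export
second_moment <- function(rect, abs_tol = 1e-6) {
  eps <- rect$eps
  n <- rect$n
  a <- rect$a
  b <- rect$b
  Z_rect <- rect_mass(rect, abs_tol)
  aFa <- vapply(seq_len(n), function(k) {
    if (is.finite(a[k]))
      a[k] * marginal_univariate(k, a[k], rect, abs_tol, Z_rect) else 0
  }, numeric(1))
  bFb <- vapply(seq_len(n), function(k) {
    if (is.finite(b[k]))
      b[k] * marginal_univariate(k, b[k], rect, abs_tol, Z_rect) else 0
  }, numeric(1))
  corner <- function(k, q, u, v) {
    if (!is.finite(u) || !is.finite(v)) return(0)
    marginal_bivariate(k, q, u, v, rect, abs_tol, Z_rect)
  }
  # pair-level four-corner combinations, independent of (i, j)
  C <- matrix(0, n, n)
  if (n >= 2) {
    for (k in seq_len(n - 1)) {
      for (q in (k + 1):n) {
        C[k, q] <- corner(k, q, a[k], a[q]) + corner(k, q, b[k], b[q]) -
          corner(k, q, a[k], b[q]) - corner(k, q, b[k], a[q])
      }
    }
  }
  E <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s1 <- sum(eps[i, ] * eps[j, ] / diag(eps) * (aFa - bFb))
      s2 <- 0
      if (n >= 2) {
        for (k in seq_len(n - 1)) {
          for (q in (k + 1):n) {
            if (C[k, q] == 0) next
            br <- eps[i, k] / eps[k, k] * (eps[k, k] * eps[j, q] -
                                             eps[k, q] * eps[j, k]) +
              eps[i, q] / eps[q, q] * (eps[q, q] * eps[j, k] -
                                         eps[q, k] * eps[j, q])
            s2 <- s2 + br * C[k, q]
          }
        }
      }
      E[i, j] <- eps[i, j] + s1 + s2
    }
  }
  (E + t(E)) / 2
}
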