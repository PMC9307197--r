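#' Deterministic quadrature reference for low dimensions
#'
#' Independent brute-force reference for `Z`, `muT` and `SigmaT`, intended
#' for validating the estimation routes at `n <= 3`. The innermost
#' coordinate is integrated in closed form: conditional on the remaining
#' coordinates, `x_1` is univariate normal, and its zeroth, first and
#' second partial moments over `[0, 1 - sum(rest)]` are pnorm/dnorm
#' expressions. The remaining coordinates are integrated by nested
#' adaptive 1-D quadrature following the nested integration limits of the
#' simplex region, with each range clipped to 40 conditional standard
#' deviations around the conditional mean so that arbitrarily
#' concentrated distributions are resolved. At `n = 1` everything is
#' closed form. The route shares no code with the three estimation
#' methods.
#'
#' @param params a [gaussian_params()] object with `n <= 3`.
#' @param abs_tol quadrature tolerance; default `1e-8` for `n <= 2` and
#'   `1e-6` for `n = 3`.
#' @return an [new_stmnd_summary()] object with method `"oracle"`.
#' @examples
#' p <- gaussian_params(c(0.45, 0.28), matrix(c(0.17, 0.04, 0.04, 0.06), 2))
#' oracle_summary(p)$Z
#' @export
oracle_summary <- function(params, abs_tol = NULL) {
  stopifnot(is_gaussian_params(params))
  n <- params$n
  if (n > 3) stop("the quadrature oracle supports n <= 3 only", call. = FALSE)
  abs_tol <- abs_tol %||% if (n <= 2) 1e-8 else 1e-6
  out <- switch(as.character(n),
                "1" = oracle_1d(params),
                "2" = oracle_2d(params, abs_tol),
                "3" = oracle_3d(params, abs_tol))
  raw <- out$raw
  muT <- out$first / out$Z
  rawSecond <- raw / out$Z
  SigmaT <- rawSecond - outer(muT, muT)
  new_stmnd_summary(Z = out$Z, muT = muT, SigmaT = SigmaT, method = "oracle",
                    rawSecond = rawSecond,
                    diagnostics = list(abs_tol = abs_tol))
}

# Partial moments of N(m, s^2) over [lo, hi]: integrals of x^p * density,
# p = 0, 1, 2. Vectorised over m and hi.
trunc_partial_moments <- function(m, s, lo, hi) {
  alpha <- (lo - m) / s
  beta <- (hi - m) / s
  delta <- stats::pnorm(beta) - stats::pnorm(alpha)
  da <- stats::dnorm(alpha)
  db <- stats::dnorm(beta)
  list(I0 = delta,
       I1 = m * delta + s * (da - db),
       I2 = (m^2 + s^2) * delta + s * ((lo + m) * da - (hi + m) * db))
}

oracle_1d <- function(params) {
  m <- params$mu[1]
  s <- sqrt(params$sigma[1, 1])
  pm <- trunc_partial_moments(m, s, 0, 1)
  list(Z = pm$I0, first = pm$I1, raw = matrix(pm$I2, 1, 1))
}

# Conditional law of x1 given the remaining coordinates.
cond_split <- function(params) {
  mu <- params$mu
  S <- params$sigma
  S_rr <- S[-1, -1, drop = FALSE]
  w <- solve(S_rr, S[-1, 1])                 # regression weights
  s2 <- S[1, 1] - sum(S[1, -1] * w)
  list(mu1 = mu[1], mu_r = mu[-1], w = w, s = sqrt(s2), S_rr = S_rr)
}

# Clip an integration range [lo_dom, hi_dom] to +/- 40 standard
# deviations around the (conditional) mean; if the Gaussian sits far
# outside the domain, keep the domain edge nearest to it.
clip_range <- function(lo_dom, hi_dom, m, s) {
  lo <- max(lo_dom, m - 40 * s)
  hi <- min(hi_dom, m + 40 * s)
  if (hi <= lo) {
    if (m < lo_dom) {
      lo <- lo_dom
      hi <- min(hi_dom, lo_dom + 80 * s)
    } else {
      hi <- hi_dom
      lo <- max(lo_dom, hi_dom - 80 * s)
    }
  }
  c(lo, hi)
}

oracle_2d <- function(params, abs_tol) {
  cs <- cond_split(params)
  s2 <- sqrt(cs$S_rr[1, 1])
  piece <- function(x2, p, mono) {
    m <- cs$mu1 + cs$w * (x2 - cs$mu_r)
    pm <- trunc_partial_moments(m, cs$s, 0, pmax(1 - x2, 0))
    inner <- switch(p + 1L, pm$I0, pm$I1, pm$I2)
    stats::dnorm(x2, cs$mu_r, s2) * inner * mono(x2)
  }
  rng <- clip_range(0, 1, cs$mu_r, s2)
  quad <- function(p, mono = function(x2) 1) {
    stats::integrate(function(x2) piece(x2, p, mono), rng[1], rng[2],
                     rel.tol = abs_tol, abs.tol = abs_tol / 10,
                     subdivisions = 500L)$value
  }
  Z <- quad(0)
  E1 <- quad(1)
  E2 <- quad(0, function(x2) x2)
  E11 <- quad(2)
  E12 <- quad(1, function(x2) x2)
  E22 <- quad(0, function(x2) x2^2)
  list(Z = Z, first = c(E1, E2),
       raw = matrix(c(E11, E12, E12, E22), 2, 2))
}

oracle_3d <- function(params, abs_tol) {
  cs <- cond_split(params)                 # x1 | (x2, x3)
  S23 <- cs$S_rr
  s3 <- sqrt(S23[2, 2])                    # marginal sd of x3
  w23 <- S23[1, 2] / S23[2, 2]             # regression of x2 on x3
  s2c <- sqrt(S23[1, 1] - w23 * S23[1, 2]) # sd of x2 | x3
  mu2 <- cs$mu_r[1]
  mu3 <- cs$mu_r[2]
  piece <- function(x2, x3, p, mono) {
    m <- cs$mu1 + cs$w[1] * (x2 - mu2) + cs$w[2] * (x3 - mu3)
    pm <- trunc_partial_moments(m, cs$s, 0, pmax(1 - x2 - x3, 0))
    inner <- switch(p + 1L, pm$I0, pm$I1, pm$I2)
    inner * mono(x2, x3)
  }
  inner_int <- function(x3, p, mono) {
    m2 <- mu2 + w23 * (x3 - mu3)
    r2 <- clip_range(0, 1 - x3, m2, s2c)
    if (r2[2] <= r2[1]) return(0)
    stats::integrate(function(x2)
      stats::dnorm(x2, m2, s2c) * piece(x2, x3, p, mono),
      r2[1], r2[2], rel.tol = abs_tol, abs.tol = abs_tol / 10,
      subdivisions = 500L)$value
  }
  rng3 <- clip_range(0, 1, mu3, s3)
  quad <- function(p, mono = function(x2, x3) 1) {
    stats::integrate(function(x3) {
      vapply(x3, function(v)
        stats::dnorm(v, mu3, s3) * inner_int(v, p, mono), numeric(1))
    }, rng3[1], rng3[2], rel.tol = abs_tol, abs.tol = abs_tol / 10,
    subdivisions = 500L)$value
  }
  Z <- quad(0)
  E1 <- quad(1)
  E2 <- quad(0, function(x2, x3) x2)
  E3 <- quad(0, function(x2, x3) x3)
  E11 <- quad(2)
  E12 <- quad(1, function(x2, x3) x2)
  E13 <- quad(1, function(x2, x3) x3)
  E22 <- quad(0, function(x2, x3) x2^2)
  E23 <- quad(0, function(x2, x3) x2 * x3)
  E33 <- quad(0, function(x2, x3) x3^2)
  raw <- matrix(c(E11, E12, E13,
                  E12, E22, E23,
                  E13, E23, E33), 3, 3)
  list(Z = Z, first = c(E1, E2, E3), raw = raw)
}
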