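#' Feasible arcs of an ellipse inside a linear-constraint domain
#'
#' For the ellipse `y*(theta) = y_t cos(theta) + nu sin(theta)` and the
#' constraint system `A y + c' >= 0`, each constraint row `j` restricts
#' `theta` through `r_j cos(theta - phi_j) >= -c'_j`, with
#' `r_j = sqrt((a_j.y_t)^2 + (a_j.nu)^2)` and
#' `phi_j = atan2(a_j.nu, a_j.y_t)`. Its feasible set is therefore the full
#' circle (when `c'_j >= r_j`), empty (when `c'_j <= -r_j`; excluded by the
#' precondition that `y_t` is feasible) or a single arc of half-width
#' `acos(-c'_j / r_j)` centred on `phi_j`. The returned arc set is the
#' intersection across all rows, normalised to disjoint intervals within
#' `[0, 2 pi)` (an arc wrapping the origin is split in two).
#'
#' @param y_t current (feasible) state in centred coordinates.
#' @param nu auxiliary Gaussian vector defining the ellipse.
#' @param domain a [simplex_domain()] (or any list with `A`, `c_prime`).
#' @param tol feasibility tolerance; a constraint with `r_j` below
#'   `tol * (1 + |c'_j|)` is treated as theta-independent.
#' @return a list of class `arc_set` with `intervals` (two-column matrix
#'   of `(lo, hi)` pairs) and `total_measure`.
#' @export
feasible_arcs <- function(y_t, nu, domain, tol = 1e-12) {
  fa <- feasible_arcs_(as.numeric(domain$A %*% y_t),
                       as.numeric(domain$A %*% nu),
                       domain$c_prime, tol)
  ord <- order(fa$lo)
  structure(list(intervals = cbind(lo = fa$lo[ord], hi = fa$hi[ord]),
                 total_measure = sum(fa$hi - fa$lo)),
            class = "arc_set")
}

# Hot path shared with ess_step: flat lo/hi interval vectors within
# [0, 2 pi), intersected constraint by constraint.
feasible_arcs_ <- function(u, v, cp, tol = 1e-12) {
  two_pi <- 2 * pi
  r <- sqrt(u^2 + v^2)
  lo <- 0
  hi <- two_pi
  for (j in seq_along(cp)) {
    if (r[j] < tol * (1 + abs(cp[j]))) {
      # theta-independent constraint: feasible everywhere or nowhere
      if (cp[j] >= -tol) next
      stop("infeasible state: a theta-independent constraint is violated",
           call. = FALSE)
    }
    if (cp[j] >= r[j]) next                      # whole ellipse feasible
    if (cp[j] <= -r[j]) {
      stop("infeasible state: current point violates a constraint",
           call. = FALSE)
    }
    phi <- atan2(v[j], u[j])
    half <- acos(min(1, max(-1, -cp[j] / r[j])))
    # feasible arc [phi - half, phi + half], split at the origin wrap
    s <- (phi - half) %% two_pi
    e <- s + 2 * half
    if (e <= two_pi) {
      p_lo <- s
      p_hi <- e
    } else {
      p_lo <- c(0, s)
      p_hi <- c(e - two_pi, two_pi)
    }
    # clip current intervals against the (1 or 2) arc pieces
    nl <- c(pmax(lo, p_lo[1]), if (length(p_lo) > 1) pmax(lo, p_lo[2]))
    nh <- c(pmin(hi, p_hi[1]), if (length(p_hi) > 1) pmin(hi, p_hi[2]))
    keep <- nh > nl
    lo <- nl[keep]
    hi <- nh[keep]
    if (length(lo) == 0) {
      stop("infeasible state: empty arc intersection (caller bug or tolerance too aggressive)",
           call. = FALSE)
    }
  }
  list(lo = lo, hi = hi)
}

#' One elliptical-slice-sampling step under linear constraints
#'
#' Draws the auxiliary vector `nu ~ N(0, Sigma)`, computes the feasible
#' arcs of the resulting ellipse analytically, draws `theta*` uniformly
#' over the union of arcs (interval chosen with probability proportional
#' to its length, then uniform within), and returns
#' `y_t cos(theta*) + nu sin(theta*)`. Every step is accepted: the new
#' state is feasible by construction. Arc endpoints are shrunk inward by
#' `1e-12` radians so the returned state stays strictly feasible under
#' floating point.
#'
#' @param y_t current feasible state (centred coordinates).
#' @param params a [gaussian_params()] object (supplies Sigma).
#' @param domain a [simplex_domain()] object.
#' @return the next state, a length-`n` vector.
#' @export
ess_step <- function(y_t, params, domain) {
  nu <- as.numeric(params$L %*% stats::rnorm(params$n))
  fa <- feasible_arcs_(as.numeric(domain$A %*% y_t),
                       as.numeric(domain$A %*% nu),
                       domain$c_prime)
  lo <- fa$lo
  hi <- fa$hi
  shrink <- 1e-12
  wide <- (hi - lo) > 2 * shrink
  if (any(wide)) {
    lo <- lo[wide] + shrink
    hi <- hi[wide] - shrink
  }
  len <- hi - lo
  u <- stats::runif(1) * sum(len)
  cum <- cumsum(len)
  k <- which(u <= cum)[1]
  theta <- hi[k] - (cum[k] - u)
  y_t * cos(theta) + nu * sin(theta)
}

#' Deterministic interior starting point for the simplex domain
#'
#' Returns `y0 = x0 - mu` with `x0 = rep(1/(2n), n)`: strictly interior to
#' the exact simplex domain (coordinates positive, sum one half) and hence
#' to every loosened domain.
#'
#' @param params a [gaussian_params()] object.
#' @param domain a [simplex_domain()] object (used for its dimension only).
#' @return a length-`n` vector in centred coordinates.
#' @export
initial_point <- function(params, domain) {
  rep(1 / (2 * params$n), params$n) - params$mu
}

#' Rejection-free Markov chain sampling from a truncated Gaussian
#'
#' Runs the constrained elliptical slice sampler from [initial_point()],
#' discards `burn_in` steps, then keeps every `thin`-th state until
#' `n_keep` states are kept, and maps them back to original coordinates
#' `x = y + mu`. Consecutive chain states are correlated; thinning (the
#' default elsewhere in the package is every second state for moment
#' estimation) reduces but does not remove that correlation.
#'
#' @param params a [gaussian_params()] object.
#' @param domain a [simplex_domain()] object (possibly loosened).
#' @param n_keep number of states to keep.
#' @param thin keep every `thin`-th post-burn-in state (default 2).
#' @param burn_in discarded initial steps (default 100).
#' @param seed integer seed (`NULL` to continue the current RNG stream).
#' @param y0 optional feasible starting state overriding [initial_point()].
#' @return an `n_keep x n` matrix of samples in x-coordinates.
#' @examples
#' p <- gaussian_params(c(0.45, 0.28), matrix(c(0.17, 0.04, 0.04, 0.06), 2))
#' x <- sample_lin_ess(p, simplex_domain(p), n_keep = 100, seed = 1)
#' colMeans(x)
#' @export
sample_lin_ess <- function(params, domain, n_keep, thin = 2, burn_in = 100,
                           seed = NULL, y0 = NULL) {
  stopifnot(is_gaussian_params(params), n_keep >= 1, thin >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  y <- y0 %||% initial_point(params, domain)
  for (i in seq_len(burn_in)) y <- ess_step(y, params, domain)
  out <- matrix(NA_real_, nrow = n_keep, ncol = params$n)
  kept <- 0L
  step <- 0L
  while (kept < n_keep) {
    y <- ess_step(y, params, domain)
    step <- step + 1L
    if (step %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- y
    }
  }
  sweep(out, 2, params$mu, `+`)
}
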