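#' Settings for the Gessner-style integral estimator
#'
#' Defaults follow the recommendations adopted in the reference study:
#' conditional-probability target `rho_target = 0.5` (maximum-entropy
#' choice for the inside/outside indicator), `M_subset = 16` samples per
#' subset-simulation level with thinning 10 (the nested-domain schedule
#' only needs to be roughly right), and a much larger `M_hdr = 1e4`
#' samples with thinning 2 for the unbiased integral estimate and for the
#' moment estimates.
#'
#' @param rho_target target conditional probability per level, in (0, 1).
#' @param M_subset samples per subset-simulation level (>= 2).
#' @param M_hdr samples per HDR level and for moment estimation (>= 2).
#' @param thin_subset thinning ratio inside subset simulation.
#' @param thin_main thinning ratio in HDR and moment sampling.
#' @param burn_in burn-in steps for the moment-sampling chain.
#' @param seed master seed; independent child streams are derived from it
#'   for subset simulation, HDR and moment sampling.
#' @return a list of class `gessner_settings`.
#' @export
gessner_settings <- function(rho_target = 0.5, M_subset = 16, M_hdr = 1e4,
                             thin_subset = 10, thin_main = 2,
                             burn_in = 100, seed = 1L) {
  stopifnot(rho_target > 0, rho_target < 1, M_subset >= 2, M_hdr >= 2,
            thin_subset >= 1, thin_main >= 1, burn_in >= 0)
  structure(list(rho_target = rho_target,
                 M_subset = as.integer(M_subset),
                 M_hdr = as.integer(M_hdr),
                 thin_subset = as.integer(thin_subset),
                 thin_main = as.integer(thin_main),
                 burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "gessner_settings")
}

#' Shift values of centred samples relative to the simplex constraints
#'
#' For each sample `y_m` (centred coordinates) returns
#' `g_m = -min(A y_m + c)` with `A`, `c` the exact (`gamma = 0`) simplex
#' constraint system. `g_m <= 0` iff the point lies in the exact domain,
#' and `g_m < gamma` iff it lies strictly inside the `gamma`-loosened
#' domain, so the shift value is the natural level-set coordinate for the
#' nested domains.
#'
#' @param samples matrix with one centred sample per row (or a vector).
#' @param params a [gaussian_params()] object.
#' @return numeric vector of shift values.
#' @export
shift_values <- function(samples, params) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (ncol(samples) != params$n) stop("dimension mismatch", call. = FALSE)
  dom <- simplex_domain(params, 0)
  vals <- samples %*% t(dom$A)            # one row per sample, m columns
  vals <- sweep(vals, 2, dom$c, `+`)
  -apply(vals, 1, min)
}

#' Adaptive nested-domain schedule via subset simulation
#'
#' Builds a decreasing sequence of loosening shifts
#' `gamma_1 > gamma_2 > ... > gamma_S = 0` such that each conditional
#' probability `p(L_s | L_(s-1))` is close to `rho_target`. Level 0 uses
#' unconstrained Gaussian draws; each subsequent level resamples with the
#' constrained elliptical slice sampler inside the previous loosened
#' domain. The next shift is the midpoint of the `k`-th and `(k+1)`-th
#' order statistics of the current shift values, `k = ceiling(rho * M)`,
#' clamped at zero; the accumulated log-probability is the (biased)
#' subset-simulation estimate of `log Z`.
#'
#' @param params a [gaussian_params()] object.
#' @param settings a [gessner_settings()] object.
#' @param seed optional seed overriding `settings$seed`.
#' @return a list of class `nested_schedule` with `gammas`, `S`, `p_s`
#'   and `logZ`.
#' @export
subset_simulation <- function(params, settings = gessner_settings(),
                              seed = NULL) {
  stopifnot(is_gaussian_params(params))
  withr::local_seed(seed %||% derive_seed(settings$seed, "subset"))
  M <- settings$M_subset
  y <- rmvn_chol(M, rep(0, params$n), params$L)
  logZ <- 0
  gammas <- numeric(0)
  p_s <- numeric(0)
  max_levels <- 200L
  repeat {
    if (length(gammas) >= max_levels) {
      stop("subset simulation failed to reach the exact domain within 200 levels",
           call. = FALSE)
    }
    g <- shift_values(y, params)
    gs <- sort(g)
    k <- min(max(ceiling(settings$rho_target * M), 1L), M - 1L)
    gam <- (gs[k] + gs[k + 1]) / 2
    if (gam < 0) gam <- 0
    # final level is boundary-inclusive, matching in_domain()
    cnt <- if (gam == 0) sum(g <= 0) else sum(g < gam)
    if (cnt == 0) {
      stop("subset simulation produced a level containing no samples",
           call. = FALSE)
    }
    gammas <- c(gammas, gam)
    p_s <- c(p_s, cnt / M)
    logZ <- logZ + log(cnt) - log(M)
    if (gam == 0) break
    seed_state <- y[which.min(g), ]   # a current sample inside the new level
    dom <- simplex_domain(params, gam)
    x <- sample_lin_ess(params, dom, n_keep = M, thin = settings$thin_subset,
                        burn_in = 0, seed = NULL, y0 = seed_state)
    y <- sweep(x, 2, params$mu, `-`)
  }
  structure(list(gammas = gammas, S = length(gammas), p_s = p_s, logZ = logZ),
            class = "nested_schedule")
}

#' Unbiased log-integral via the Holmes-Diaconis-Ross algorithm
#'
#' Re-runs the level loop of [subset_simulation()] with the nested-domain
#' schedule held fixed (so the estimate is unbiased) and a larger number
#' of samples per level. Level 0 uses `M_hdr` unconstrained Gaussian
#' draws; level `s >= 1` draws `M_hdr` constrained-slice-sampling states
#' inside the `gamma_s`-loosened domain and counts the fraction already
#' inside the next level.
#'
#' @param params a [gaussian_params()] object.
#' @param schedule a `nested_schedule` from [subset_simulation()] for the
#'   same distribution.
#' @param settings a [gessner_settings()] object.
#' @param seed optional seed overriding the derived HDR stream.
#' @return scalar `logZ` with attribute `p_s` (per-level conditional
#'   probability estimates).
#' @export
hdr <- function(params, schedule, settings = gessner_settings(), seed = NULL) {
  stopifnot(is_gaussian_params(params), inherits(schedule, "nested_schedule"))
  withr::local_seed(seed %||% derive_seed(settings$seed, "hdr"))
  M <- settings$M_hdr
  gammas <- schedule$gammas
  logZ <- 0
  var_logZ <- 0
  p_s <- numeric(0)
  for (s in seq_along(gammas)) {
    if (s == 1) {
      y <- rmvn_chol(M, rep(0, params$n), params$L)
    } else {
      dom <- simplex_domain(params, gammas[s - 1])
      x <- sample_lin_ess(params, dom, n_keep = M, thin = settings$thin_main,
                          burn_in = 0, seed = NULL,
                          y0 = initial_point(params, dom))
      y <- sweep(x, 2, params$mu, `-`)
    }
    g <- shift_values(y, params)
    gam <- gammas[s]
    ind <- if (gam == 0) (g <= 0) else (g < gam)
    cnt <- sum(ind)
    if (cnt == 0) {
      stop(sprintf(paste0("HDR level %d contains no samples; increase M_hdr ",
                          "(log of zero is not representable)"), s),
           call. = FALSE)
    }
    p_s <- c(p_s, cnt / M)
    logZ <- logZ + log(cnt) - log(M)
    # batch-means variance of log p_s, robust to chain autocorrelation
    var_logZ <- var_logZ + batch_var_mean(as.numeric(ind)) / (cnt / M)^2
  }
  structure(logZ, p_s = p_s, se_logZ = sqrt(var_logZ))
}

# Variance of the mean of a (possibly autocorrelated) sequence by the
# method of batch means with nb contiguous batches.
batch_var_mean <- function(x, nb = 25L) {
  m <- length(x)
  nb <- min(nb, m)
  idx <- ceiling(seq_along(x) / (m / nb))
  bm <- tapply(x, idx, mean)
  stats::var(as.numeric(bm)) / length(bm)
}

#' Full Gessner-route estimate of the ST-MND summary
#'
#' Estimates `Z` as `exp(logZ)` from subset simulation followed by HDR,
#' and the truncated mean and covariance from `M_hdr` constrained
#' elliptical-slice-sampling draws in the exact (`gamma = 0`) domain with
#' thinning `thin_main` and the configured burn-in. Subset simulation,
#' HDR and moment sampling use independent RNG streams derived from the
#' master seed, all recorded in the diagnostics.
#'
#' @param params a [gaussian_params()] object.
#' @param settings a [gessner_settings()] object.
#' @return an [new_stmnd_summary()] object with the level schedule in its
#'   diagnostics.
#' @examples
#' p <- gaussian_params(c(0.45, 0.28), matrix(c(0.17, 0.04, 0.04, 0.06), 2))
#' s <- estimate_gessner(p, gessner_settings(M_hdr = 2000, seed = 7))
#' s$Z
#' @export
estimate_gessner <- function(params, settings = gessner_settings()) {
  stopifnot(is_gaussian_params(params))
  if (params$n < 2) stop("ST-MND estimation requires dimension n >= 2",
                         call. = FALSE)
  schedule <- subset_simulation(params, settings)
  logZ <- hdr(params, schedule, settings)
  dom <- simplex_domain(params, 0)
  x <- sample_lin_ess(params, dom, n_keep = settings$M_hdr,
                      thin = settings$thin_main, burn_in = settings$burn_in,
                      seed = derive_seed(settings$seed, "moments"))
  muT <- colMeans(x)
  SigmaT <- stats::cov(x)
  # batch-means standard errors for the chain-based moment estimates
  se_muT <- sqrt(vapply(seq_len(params$n),
                        function(j) batch_var_mean(x[, j]), numeric(1)))
  n <- params$n
  se_SigmaT <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      prod_ij <- (x[, i] - muT[i]) * (x[, j] - muT[j])
      se_SigmaT[i, j] <- se_SigmaT[j, i] <- sqrt(batch_var_mean(prod_ij))
    }
  }
  Z <- exp(as.numeric(logZ))
  new_stmnd_summary(
    Z = Z, logZ = as.numeric(logZ),
    muT = muT, SigmaT = SigmaT, method = "gessner",
    rawSecond = SigmaT + outer(muT, muT),
    diagnostics = list(schedule = schedule,
                       hdr_p_s = attr(logZ, "p_s"),
                       se_Z = Z * attr(logZ, "se_logZ"),
                       se_logZ = attr(logZ, "se_logZ"),
                       se_muT = se_muT, se_SigmaT = se_SigmaT,
                       settings = unclass(settings))
  )
}
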