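#' Naive rejection sampling from the ST-MND
#'
#' Draws from the untruncated Gaussian `N(mu, Sigma)` and keeps draws that
#' fall inside the simplex domain, until `M` draws have been kept. The
#' acceptance ratio `m_kept / m_total` is an unbiased estimator of the
#' integral `Z`, and the kept draws are exact ST-MND samples. Draws are
#' generated in vectorised batches; a trial budget guards against the
#' regime `Z << 1`, where this method is impractically slow and the
#' Gessner route should be used instead.
#'
#' @param params a [gaussian_params()] object.
#' @param M number of kept samples required (>= 1).
#' @param seed integer seed; the draw sequence is reproducible given it.
#' @param max_trials budget on total draws; default
#'   `max(1e7, 1e3 * M)`.
#' @return a list of class `rejection_result` with `samples` (`M x n`
#'   matrix of kept draws), `m_kept`, `m_total`, `M` and `seed`.
#' @examples
#' p <- gaussian_params(c(0.45, 0.28), matrix(c(0.17, 0.04, 0.04, 0.06), 2))
#' r <- sample_rejection(p, M = 500, seed = 1)
#' r$m_kept / r$m_total  # estimate of Z
#' @export
sample_rejection <- function(params, M, seed = 1L,
                             max_trials = max(1e7, 1e3 * M)) {
  stopifnot(is_gaussian_params(params))
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  if (max_trials < M) stop("max_trials must be >= M", call. = FALSE)
  withr::local_seed(seed)
  n <- params$n
  kept <- matrix(NA_real_, nrow = M, ncol = n)
  m_kept <- 0L
  m_total <- 0
  batch <- as.integer(min(max(2 * M, 1000), 1e5))
  while (m_kept < M) {
    if (m_total >= max_trials) {
      stop(sprintf(paste0(
        "rejection sampling budget exhausted: %d kept of %d requested ",
        "after %.0f trials; the integral Z is likely too small for this ",
        "method - use method = \"gessner\" instead"),
        m_kept, M, m_total), call. = FALSE)
    }
    nb <- as.integer(min(batch, max_trials - m_total))
    x <- rmvn_chol(nb, params$mu, params$L)
    inside <- in_domain(x, params, gamma = 0)
    hits <- which(inside)
    take <- head(hits, M - m_kept)
    # trials beyond the M-th acceptance do not count towards m_total,
    # matching the sequential sampler exactly
    if (length(take) > 0 && length(hits) >= (M - m_kept)) {
      m_total <- m_total + take[length(take)]
    } else {
      m_total <- m_total + nb
    }
    if (length(take) > 0) {
      kept[(m_kept + 1):(m_kept + length(take)), ] <- x[take, , drop = FALSE]
      m_kept <- m_kept + length(take)
    }
  }
  structure(
    list(samples = kept, m_kept = m_kept, m_total = m_total,
         M = as.integer(M), seed = seed),
    class = "rejection_result"
  )
}

#' Summarise a rejection-sampling run
#'
#' Forms the three ST-MND estimates from a completed run: `Z` as the
#' acceptance ratio, `muT` as the sample mean of the kept draws, and
#' `SigmaT` as the sample covariance with the `M - 1` denominator.
#'
#' @param result a `rejection_result` from [sample_rejection()].
#' @return an [new_stmnd_summary()] object.
#' @export
summarise_rejection <- function(result) {
  stopifnot(inherits(result, "rejection_result"))
  if (result$M < 2) stop("at least 2 kept samples are needed for a covariance",
                         call. = FALSE)
  x <- result$samples
  muT <- colMeans(x)
  SigmaT <- stats::cov(x)
  Z <- result$m_kept / result$m_total
  M <- result$M
  # Monte-Carlo standard errors: inverse-binomial for Z, iid formulas for
  # the moments (normal approximation for the covariance elements)
  se_Z <- Z * sqrt(max(1 - Z, 0) / M)
  se_muT <- sqrt(diag(SigmaT) / M)
  se_SigmaT <- sqrt((outer(diag(SigmaT), diag(SigmaT)) + SigmaT^2) / M)
  new_stmnd_summary(
    Z = Z, muT = muT, SigmaT = SigmaT, method = "rejection",
    rawSecond = SigmaT + outer(muT, muT),
    diagnostics = list(m_kept = result$m_kept, m_total = result$m_total,
                       M = result$M, seed = result$seed,
                       se_Z = se_Z, se_muT = se_muT, se_SigmaT = se_SigmaT)
  )
}

#' Rejection-sampling estimate of the ST-MND summary
#'
#' Convenience wrapper: [sample_rejection()] followed by
#' [summarise_rejection()].
#'
#' @param params a [gaussian_params()] object.
#' @param M number of kept samples (default `1e4`).
#' @param seed integer seed.
#' @param max_trials budget on total draws.
#' @return an [new_stmnd_summary()] object.
#' @export
estimate_rejection <- function(params, M = 1e4, seed = 1L,
                               max_trials = max(1e7, 1e3 * M)) {
  summarise_rejection(sample_rejection(params, M = M, seed = seed,
                                       max_trials = max_trials))
}
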