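#' Estimate the integral, mean and covariance of an ST-MND
#'
#' Single entry point dispatching to one of the three estimation routes:
#'
#' * `"rejection"` - naive rejection sampling from the untruncated
#'   Gaussian (simple, unbiased, impractical for small `Z`); settings
#'   `M` (kept samples, default `1e4`), `seed`, `max_trials`.
#' * `"gessner"` - constrained elliptical slice sampling combined with
#'   subset simulation and the Holmes-Diaconis-Ross estimator
#'   (rejection-free, scales to higher dimension and tiny `Z`); settings
#'   as in [gessner_settings()].
#' * `"semi_analytical"` - deterministic inclusion-exclusion over
#'   rectangle probabilities (fastest at low dimension, cost
#'   exponential in `n`); settings `abs_tol` (default `1e-6`),
#'   `max_dim` (default 6).
#'
#' The settings actually used, including derived seeds, are recorded in
#' the returned diagnostics; equal inputs, method, and seed give equal
#' output.
#'
#' @param params a [gaussian_params()] object with `n >= 2`.
#' @param method one of `"semi_analytical"`, `"rejection"`, `"gessner"`.
#' @param settings named list of method-specific settings (see above).
#' @return an [new_stmnd_summary()] object.
#' @examples
#' p <- gaussian_params(c(0.45, 0.28), matrix(c(0.17, 0.04, 0.04, 0.06), 2))
#' estimate(p, "semi_analytical")$Z
#' @export
estimate <- function(params,
                     method = c("semi_analytical", "rejection", "gessner"),
                     settings = list()) {
  stopifnot(is_gaussian_params(params))
  method <- match.arg(method)
  if (params$n < 2) {
    stop("ST-MND estimation requires dimension n >= 2 (the n = 1 case is a univariate truncated normal with closed forms)",
         call. = FALSE)
  }
  known <- switch(method,
    rejection = c("M", "seed", "max_trials"),
    gessner = c("rho_target", "M_subset", "M_hdr", "thin_subset",
                "thin_main", "burn_in", "seed"),
    semi_analytical = c("abs_tol", "max_dim", "seed"))
  bad <- setdiff(names(settings), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown settings for method '%s': %s", method,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- switch(method,
    rejection = {
      M <- settings$M %||% 1e4
      estimate_rejection(params, M = M, seed = settings$seed %||% 1L,
                         max_trials = settings$max_trials %||%
                           max(1e7, 1e3 * M))
    },
    gessner = {
      gs <- do.call(gessner_settings, settings)
      estimate_gessner(params, gs)
    },
    semi_analytical = estimate_semi_analytical(
      params, abs_tol = settings$abs_tol %||% 1e-6,
      max_dim = settings$max_dim %||% 6))
  out$diagnostics$settings_used <- settings
  out
}
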