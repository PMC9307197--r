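#' Result container for ST-MND estimates
#'
#' All three estimation routes return an object of class `stmnd_summary`
#' holding the normalising integral `Z` (the probability mass of the
#' untruncated Gaussian inside the simplex domain), the truncated mean
#' `muT`, the truncated covariance `SigmaT`, the raw second-moment matrix
#' `rawSecond = E(X X^T)` (so `SigmaT = rawSecond - muT muT^T` identically),
#' a `method` tag and a method-specific `diagnostics` record (sample
#' counts, level schedule, tolerances, seeds actually used).
#'
#' @param Z scalar integral estimate in (0, 1).
#' @param muT length-`n` truncated mean.
#' @param SigmaT `n x n` truncated covariance.
#' @param method method tag, one of `"rejection"`, `"gessner"`,
#'   `"semi_analytical"`, `"oracle"`.
#' @param rawSecond optional raw second-moment matrix; reconstructed from
#'   `SigmaT` and `muT` when omitted.
#' @param logZ optional log of `Z` (kept exactly for tiny integrals).
#' @param diagnostics named list of method-specific diagnostics.
#' @return an `stmnd_summary` object.
#' @export
new_stmnd_summary <- function(Z, muT, SigmaT, method,
                              rawSecond = NULL, logZ = NULL,
                              diagnostics = list()) {
  muT <- as.numeric(muT)
  SigmaT <- (SigmaT + t(SigmaT)) / 2
  if (is.null(rawSecond)) rawSecond <- SigmaT + outer(muT, muT)
  structure(
    list(Z = as.numeric(Z),
         logZ = logZ %||% log(as.numeric(Z)),
         muT = muT,
         SigmaT = SigmaT,
         rawSecond = (rawSecond + t(rawSecond)) / 2,
         method = method,
         diagnostics = diagnostics),
    class = "stmnd_summary"
  )
}

#' @export
print.stmnd_summary <- function(x, ...) {
  cat(sprintf("<stmnd_summary: %s> n = %d\n", x$method, length(x$muT)))
  cat(sprintf("Z    = %.6g  (logZ = %.6g)\n", x$Z, x$logZ))
  cat("muT  = ", paste(signif(x$muT, 5), collapse = ", "), "\n")
  cat("SigmaT:\n")
  print(signif(x$SigmaT, 5))
  invisible(x)
}

#' Tidy an ST-MND summary into one row per estimated quantity
#'
#' Broom-style accessor: returns a tibble with one row per scalar quantity
#' (`Z`, each mean element, each upper-triangle covariance element),
#' suitable for joining estimates across methods.
#'
#' @param x an `stmnd_summary` object.
#' @param ... unused.
#' @return a tibble with columns `quantity`, `i`, `j`, `estimate`, `method`.
#' @export
#' @method tidy stmnd_summary
tidy.stmnd_summary <- function(x, ...) {
  n <- length(x$muT)
  ut <- which(upper.tri(x$SigmaT, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    quantity = c("Z", rep("muT", n), rep("SigmaT", nrow(ut))),
    i = c(NA_integer_, seq_len(n), ut[, 1]),
    j = c(NA_integer_, rep(NA_integer_, n), ut[, 2]),
    estimate = c(x$Z, x$muT, x$SigmaT[ut]),
    method = x$method
  )
}

#' Glance at an ST-MND summary
#'
#' @param x an `stmnd_summary` object.
#' @param ... unused.
#' @return a one-row tibble with `method`, `n`, `Z`, `logZ` and the trace
#'   of the truncated covariance.
#' @export
#' @method glance stmnd_summary
glance.stmnd_summary <- function(x, ...) {
  tibble::tibble(method = x$method, n = length(x$muT),
                 Z = x$Z, logZ = x$logZ,
                 trace_SigmaT = sum(diag(x$SigmaT)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Internal invariant check used by tests and by estimate(): a proper
# summary has Z in (0,1), a mean inside the closed simplex domain, a
# (numerically) PSD covariance with variances bounded by 1/4, and a raw
# second moment consistent with mean and covariance.
check_summary_invariants <- function(s, tol = 1e-8) {
  ok <- list(
    Z_in_unit = s$Z > 0 && s$Z < 1,
    mean_nonneg = all(s$muT >= -tol),
    mean_sum = sum(s$muT) <= 1 + tol,
    cov_sym = max(abs(s$SigmaT - t(s$SigmaT))) <= tol,
    cov_psd = min(eigen(s$SigmaT, symmetric = TRUE,
                        only.values = TRUE)$values) >= -tol,
    var_bound = all(diag(s$SigmaT) <= 0.25 + tol),
    raw_consistent = max(abs(s$rawSecond - (s$SigmaT + outer(s$muT, s$muT)))) <= tol
  )
  ok
}
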