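#' Configuration of the random benchmark-problem generator
#'
#' The generator reproduces the study conditions used to compare the
#' three estimation routes: the mean is uniform in the unit simplex
#' (accept/reject from `U(0, 1)^n`), variances are `U(0, 0.25)` (a
#' plausible spread for compositional fractions), correlations are
#' `U(-0.5, 0.5)` (wider ranges make the eigenvalue acceptance step
#' impractically slow by `n = 9`), and a sampled covariance is kept only
#' if all its eigenvalues are non-negative. Overriding a law is possible
#' but recorded in the config so downstream tables carry the deviation.
#'
#' @param n dimension (>= 2).
#' @param n_problems number of problems to generate (study default 100).
#' @param var_max upper bound of the variance law (default 0.25).
#' @param corr_range correlation law bounds (default `c(-0.5, 0.5)`).
#' @param seed integer seed.
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(n, n_problems = 100, var_max = 0.25,
                             corr_range = c(-0.5, 0.5), seed = 1L) {
  stopifnot(n >= 2, n_problems >= 1, var_max > 0,
            length(corr_range) == 2, corr_range[1] < corr_range[2])
  structure(list(n = as.integer(n), n_problems = as.integer(n_problems),
                 var_max = var_max, corr_range = corr_range,
                 seed = as.integer(seed),
                 overridden = !identical(c(var_max, corr_range),
                                         c(0.25, -0.5, 0.5))),
            class = "benchmark_config")
}

#' Draw one random benchmark distribution
#'
#' Samples `mu` uniformly in the unit simplex by accept/reject and a
#' covariance from the variance/correlation laws of the config, redrawing
#' wholesale until all eigenvalues are non-negative. A kept matrix whose
#' smallest eigenvalue fails the strict positive-definiteness floor of
#' [gaussian_params()] (a probability-zero event under continuous
#' sampling) gets `1e-10 * trace` added to its diagonal.
#'
#' @param config a [benchmark_config()] object.
#' @param seed optional seed; omit to consume the current RNG stream.
#' @return a [gaussian_params()] object.
#' @export
sample_problem <- function(config, seed = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- config$n
  budget <- 1e6
  tries <- 0
  repeat {
    mu <- stats::runif(n)
    if (sum(mu) <= 1) break
    tries <- tries + 1
    if (tries > budget) stop("mean resampling budget exhausted", call. = FALSE)
  }
  tries <- 0
  repeat {
    sii <- stats::runif(n, 0, config$var_max)
    S <- diag(sii, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- stats::runif(1, config$corr_range[1], config$corr_range[2])
        S[i, j] <- S[j, i] <- r * sqrt(sii[i] * sii[j])
      }
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev >= 0)) break
    tries <- tries + 1
    if (tries > budget) {
      stop("covariance resampling budget exhausted (correlation range too wide?)",
           call. = FALSE)
    }
  }
  if (min(ev) <= 1e-12 * sum(diag(S))) {
    message("nudging a semi-definite covariance to strict positive definiteness")
    S <- S + diag(1e-10 * sum(diag(S)), n)
  }
  gaussian_params(mu, S)
}

#' Run a cross-method comparison over random benchmark problems
#'
#' Generates `n_problems` distributions from the config, runs each
#' requested estimation route on each, and returns a tidy tibble with one
#' row per problem x method x scalar quantity (`Z`, mean elements,
#' upper-triangle covariance elements), plus wall time per fit. Failures
#' of a single fit are recorded in the `error` column rather than
#' aborting the run. Fixed seed implies fixed output.
#'
#' @param config a [benchmark_config()] object.
#' @param methods character vector from
#'   `c("rejection", "gessner", "semi_analytical")`.
#' @param settings named list of per-method settings overriding the
#'   defaults of [estimate()].
#' @return a tibble of class `stmnd_comparison` with columns `problem`,
#'   `n`, `method`, `quantity`, `i`, `j`, `estimate`, `seconds`, `error`.
#' @examples
#' cfg <- benchmark_config(2, n_problems = 2, seed = 5)
#' run_comparison(cfg, methods = "semi_analytical")
#' @export
run_comparison <- function(config,
                           methods = c("rejection", "gessner",
                                       "semi_analytical"),
                           settings = list()) {
  stopifnot(inherits(config, "benchmark_config"), length(methods) >= 1)
  methods <- match.arg(methods, c("rejection", "gessner", "semi_analytical"),
                       several.ok = TRUE)
  rows <- list()
  for (p in seq_len(config$n_problems)) {
    params <- sample_problem(config, seed = derive_seed(config$seed,
                                                        paste0("problem", p)))
    for (m in methods) {
      ms <- settings[[m]] %||% list()
      ms$seed <- ms$seed %||% derive_seed(config$seed, paste0(m, p))
      t0 <- proc.time()[["elapsed"]]
      fit <- tryCatch(estimate(params, method = m, settings = ms),
                      error = function(e) e)
      secs <- proc.time()[["elapsed"]] - t0
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          problem = p, n = config$n, method = m,
          quantity = NA_character_, i = NA_integer_, j = NA_integer_,
          estimate = NA_real_, seconds = secs,
          error = conditionMessage(fit))
      } else {
        td <- tidy(fit)
        rows[[length(rows) + 1]] <- tibble::tibble(
          problem = p, n = config$n, method = m,
          quantity = td$quantity, i = td$i, j = td$j,
          estimate = td$estimate, seconds = secs, error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stmnd_comparison", class(out))
  out
}

#' Scatter comparison of two methods' estimates
#'
#' Cross-method concordance plot: one panel per quantity type, each point
#' one estimated scalar, with the identity line. Mirrors the diagonal
#' scatter layout used to validate the three routes against each other.
#'
#' @param object an `stmnd_comparison` tibble from [run_comparison()].
#' @param x_method,y_method methods to place on the axes.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @method autoplot stmnd_comparison
autoplot.stmnd_comparison <- function(object, x_method = "rejection",
                                      y_method = "semi_analytical", ...) {
  df <- as.data.frame(object)
  df <- df[!is.na(df$quantity), ]
  key <- paste(df$problem, df$quantity, df$i, df$j)
  xs <- df[df$method == x_method, ]
  ys <- df[df$method == y_method, ]
  kx <- paste(xs$problem, xs$quantity, xs$i, xs$j)
  ky <- paste(ys$problem, ys$quantity, ys$i, ys$j)
  common <- intersect(kx, ky)
  dd <- data.frame(quantity = xs$quantity[match(common, kx)],
                   x = xs$estimate[match(common, kx)],
                   y = ys$estimate[match(common, ky)])
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = x_method, y = y_method) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
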