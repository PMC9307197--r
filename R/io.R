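#' Read distribution parameters from JSON
#'
#' Expects a JSON object `{"mu": [...], "sigma": [[...], ...]}`.
#'
#' @param path file path.
#' @return a [gaussian_params()] object.
#' @export
read_gaussian_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path),
                               call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$mu) || is.null(obj$sigma)) {
    stop("JSON input must contain fields 'mu' and 'sigma'", call. = FALSE)
  }
  gaussian_params(as.numeric(obj$mu), as.matrix(obj$sigma))
}

#' Read distribution parameters from a pair of CSV files
#'
#' `mu_path` holds one number per line; `sigma_path` holds the square
#' covariance matrix, comma-separated, no header.
#'
#' @param mu_path,sigma_path file paths.
#' @return a [gaussian_params()] object.
#' @export
read_gaussian_csv <- function(mu_path, sigma_path) {
  for (p in c(mu_path, sigma_path)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                              call. = FALSE)
  }
  mu <- as.numeric(utils::read.csv(mu_path, header = FALSE)[[1]])
  sigma <- as.matrix(utils::read.csv(sigma_path, header = FALSE))
  dimnames(sigma) <- NULL
  gaussian_params(mu, sigma)
}

#' Write an ST-MND summary to JSON
#'
#' Serialises `Z`, `logZ`, `muT`, `SigmaT`, `rawSecond`, the method tag
#' and the diagnostics record, at full decimal precision.
#'
#' @param summary an `stmnd_summary` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stmnd_json <- function(summary, path) {
  stopifnot(inherits(summary, "stmnd_summary"))
  payload <- list(Z = summary$Z, logZ = summary$logZ, muT = summary$muT,
                  SigmaT = summary$SigmaT, rawSecond = summary$rawSecond,
                  method = summary$method,
                  diagnostics = summary$diagnostics)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", force = TRUE)
  invisible(path)
}

#' Read an ST-MND summary back from JSON
#'
#' @param path file path written by [write_stmnd_json()].
#' @return an `stmnd_summary` object.
#' @export
read_stmnd_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_stmnd_summary(Z = obj$Z, muT = obj$muT,
                    SigmaT = as.matrix(obj$SigmaT),
                    rawSecond = as.matrix(obj$rawSecond),
                    logZ = obj$logZ, method = obj$method,
                    diagnostics = as.list(obj$diagnostics))
}
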