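# Shared fixtures: all problems are generated in code.

# The bivariate distribution used throughout as a worked example
# (interior mean, moderate anisotropic covariance).
worked_example_params <- function() {
  gaussian_params(c(0.45, 0.28), matrix(c(0.17, 0.04, 0.04, 0.06), 2))
}

# A random benchmark problem at dimension n, reproducible by seed.
random_problem <- function(n, seed) {
  sample_problem(benchmark_config(n, seed = seed), seed = seed)
}

# Is angle theta inside the arc set (half-open intervals)?
arc_contains <- function(arcs, theta) {
  any(theta >= arcs$intervals[, 1] & theta < arcs$intervals[, 2])
}

# Dense-grid feasibility indicator for the ellipse
# y*(theta) = y cos(theta) + nu sin(theta) against A y + c' >= 0.
grid_feasible <- function(y, nu, domain, thetas) {
  u <- as.numeric(domain$A %*% y)
  v <- as.numeric(domain$A %*% nu)
  vals <- outer(u, cos(thetas)) + outer(v, sin(thetas)) + domain$c_prime
  apply(vals >= 0, 2, all)
}

# Count grid points whose arc-set membership disagrees with direct
# feasibility; endpoint-adjacent grid points are allowed to disagree.
arc_grid_mismatches <- function(y, nu, domain, n_grid = 1e5) {
  thetas <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  feas <- grid_feasible(y, nu, domain, thetas)
  arcs <- feasible_arcs(y, nu, domain)
  lo <- arcs$intervals[, 1]
  hi <- arcs$intervals[, 2]
  inside <- colSums(outer(lo, thetas, `<=`) & outer(hi, thetas, `>`)) > 0
  sum(inside != feas)
}
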