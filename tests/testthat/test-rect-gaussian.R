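# Brute-force box integral of the Gaussian density by 2-D adaptive
# quadrature (infinite bounds cut at 10 standard deviations).
quad_box2 <- function(eps, a, b, f = function(w1, w2) 1) {
  s <- sqrt(diag(eps))
  lo <- pmax(a, -10 * s)
  hi <- pmin(b, 10 * s)
  pracma::integral2(function(x, y) {
    z <- cbind(as.vector(x), as.vector(y))
    dens <- stmnd:::dmvn(z, c(0, 0), eps)
    matrix(f(as.vector(x), as.vector(y)) * dens, nrow = nrow(x))
  }, lo[1], hi[1], lo[2], hi[2], reltol = 1e-10)$Q
}

test_that("rectangle probabilities reproduce closed forms", {
  expect_equal(rect_integral(c(-Inf, -Inf), c(Inf, Inf), c(0, 0), diag(2)), 1)
  expect_equal(rect_integral(0, Inf, 0, matrix(1)), 0.5)
  eps <- matrix(c(1, 0.5, 0.5, 1), 2)
  # orthant probability: 1/4 + asin(rho)/(2 pi) = 1/3
  p_orth <- rect_integral(c(0, 0), c(Inf, Inf), c(0, 0), eps)
  expect_equal(p_orth, 1 / 3, tolerance = 2e-6)
  expect_equal(p_orth, quad_box2(eps, c(0, 0), c(Inf, Inf)), tolerance = 2e-6)
  expect_error(rect_integral(c(0, 0), c(-1, 1), c(0, 0), diag(2)), "a < b")
})

test_that("linear constraints transform to the stated rectangle problems", {
  p <- gaussian_params(c(0.3, 0.2), diag(2))
  # identity transform: pure centring
  r <- transform_to_rect(diag(2), c(-1, -1), c(1, 1), p)
  expect_equal(r$eps, p$sigma)
  expect_equal(r$a, c(-1, -1) - p$mu)
  expect_equal(r$b, c(1, 1) - p$mu)

  # the excised half-space sum(x) > 1 written as 1 < x1 + x2 < Inf
  Tm <- rbind(c(1, 1), c(1, 0))
  r <- transform_to_rect(Tm, c(1, -Inf), c(Inf, Inf), p)
  expect_equal(r$eps, rbind(c(2, 1), c(1, 1)))
  expect_equal(r$a, c(0.5, -Inf))
  expect_equal(r$b, c(Inf, Inf))
  # integral invariance: x1 + x2 ~ N(0.5, 2), P(sum > 1) closed form
  expect_equal(rect_integral(r$a, r$b, c(0, 0), r$eps),
               1 - pnorm(0.5, 0, sqrt(2)), tolerance = 2e-6)
  expect_error(transform_to_rect(matrix(1, 2, 2), c(0, 0), c(1, 1), p),
               "full rank")
})

test_that("univariate marginal densities integrate to one and match quadrature", {
  # no truncation + independence: the marginal is the plain normal density
  r0 <- rect_gaussian(diag(2), c(-Inf, -Inf), c(Inf, Inf))
  expect_equal(marginal_univariate(1, 0.7, r0), dnorm(0.7), tolerance = 1e-9)

  r <- rect_gaussian(matrix(c(1, 0.5, 0.5, 1), 2), c(0, 0), c(1, 1))
  total <- integrate(function(w) vapply(w, function(wi)
    marginal_univariate(1, wi, r), numeric(1)), 0, 1, rel.tol = 1e-8)$value
  expect_equal(total, 1, tolerance = 1e-4)

  # n = 3: marginal at a point vs brute-force quadrature over the others
  set.seed(8)
  p3 <- random_problem(3, seed = 81)
  eps <- p3$sigma / max(diag(p3$sigma))  # any PD matrix serves
  a <- c(-0.5, -0.4, -0.6); b <- c(0.8, 0.7, 0.9)
  r3 <- rect_gaussian(eps, a, b)
  f2 <- marginal_univariate(2, 0.1, r3)
  mass <- rect_integral(a, b, rep(0, 3), eps, abs_tol = 1e-8)
  # direct 2-D quadrature of the joint density at w2 = 0.1
  direct <- pracma::integral2(function(x, y) {
    z <- cbind(as.vector(x), 0.1, as.vector(y))
    matrix(stmnd:::dmvn(z, rep(0, 3), eps), nrow = nrow(x))
  }, a[1], b[1], a[3], b[3], reltol = 1e-9)$Q
  expect_equal(f2, direct / mass, tolerance = 1e-5)
})

test_that("bivariate marginal densities are symmetric and match quadrature", {
  # n = 2: exact reduction to density over mass
  eps <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  r <- rect_gaussian(eps, c(-1, -0.5), c(0.7, 1.2))
  mass <- rect_integral(r$a, r$b, c(0, 0), eps)
  expect_equal(marginal_bivariate(1, 2, 0.2, -0.1, r),
               stmnd:::dmvn(c(0.2, -0.1), c(0, 0), eps) / mass,
               tolerance = 1e-12)

  # symmetry under swapping the conditioning pair, n = 4
  p4 <- random_problem(4, seed = 90)
  r4 <- rect_gaussian(p4$sigma, c(-0.3, -0.4, -0.2, -0.5),
                      c(0.4, 0.3, 0.5, 0.2))
  for (pair in list(c(1, 3), c(2, 4))) {
    f_kq <- marginal_bivariate(pair[1], pair[2], 0.1, -0.05, r4)
    f_qk <- marginal_bivariate(pair[2], pair[1], -0.05, 0.1, r4)
    expect_equal(f_kq, f_qk, tolerance = 1e-12)
  }

  # n = 3 vs 1-D quadrature of the joint density over the third coordinate
  p3 <- random_problem(3, seed = 91)
  eps3 <- p3$sigma
  a <- c(-0.4, -0.3, -0.5); b <- c(0.5, 0.6, 0.4)
  r3 <- rect_gaussian(eps3, a, b)
  f12 <- marginal_bivariate(1, 2, 0.1, 0.05, r3)
  mass3 <- rect_integral(a, b, rep(0, 3), eps3, abs_tol = 1e-8)
  direct <- integrate(function(w3) vapply(w3, function(w)
    stmnd:::dmvn(c(0.1, 0.05, w), rep(0, 3), eps3), numeric(1)),
    a[3], b[3], rel.tol = 1e-9)$value
  expect_equal(f12, direct / mass3, tolerance = 1e-5)
})

test_that("first rectangle moments obey symmetry and half-normal closed forms", {
  eps <- matrix(c(1, 0.4, 0.4, 1), 2)
  r_sym <- rect_gaussian(eps, c(-0.7, -0.7), c(0.7, 0.7))
  expect_equal(first_moment(r_sym), c(0, 0), tolerance = 1e-6)

  r_half <- rect_gaussian(matrix(1), 0, Inf)
  expect_equal(first_moment(r_half), sqrt(2 / pi), tolerance = 1e-7)

  # n = 3 vs rejection-sampled truncated Gaussian
  p3 <- random_problem(3, seed = 92)
  eps3 <- p3$sigma
  a <- c(-0.3, -0.2, -0.4); b <- c(0.3, 0.5, 0.2)
  r3 <- rect_gaussian(eps3, a, b)
  m <- first_moment(r3)
  withr::with_seed(14, {
    x <- stmnd:::rmvn_chol(4e5, rep(0, 3), chol_ <- t(chol(eps3)))
    keep <- x[, 1] > a[1] & x[, 1] < b[1] & x[, 2] > a[2] & x[, 2] < b[2] &
      x[, 3] > a[3] & x[, 3] < b[3]
    xs <- x[keep, ]
  })
  se <- apply(xs, 2, sd) / sqrt(nrow(xs))
  expect_true(all(abs(m - colMeans(xs)) < 4 * se))
})

test_that("second rectangle moments reproduce limits and quadrature", {
  eps <- matrix(c(1, 0.4, 0.4, 1), 2)
  r_free <- rect_gaussian(eps, c(-Inf, -Inf), c(Inf, Inf))
  expect_equal(second_moment(r_free), eps, tolerance = 1e-9)

  r_half <- rect_gaussian(matrix(1), 0, Inf)
  expect_equal(second_moment(r_half), matrix(1), tolerance = 1e-7)

  r <- rect_gaussian(eps, c(-0.5, -0.8), c(1, 0.6))
  E <- second_moment(r)
  mass <- rect_integral(r$a, r$b, c(0, 0), eps, abs_tol = 1e-8)
  for (ij in list(c(1, 1), c(1, 2), c(2, 2))) {
    direct <- quad_box2(eps, r$a, r$b,
                        f = function(w1, w2)
                          cbind(w1, w2)[, ij[1]] * cbind(w1, w2)[, ij[2]])
    expect_equal(E[ij[1], ij[2]], direct / mass, tolerance = 1e-5)
  }

  # consistency: first moment equals the integral of w * marginal density
  m1 <- first_moment(r)
  direct_m1 <- integrate(function(w) vapply(w, function(wi)
    wi * marginal_univariate(1, wi, r), numeric(1)),
    r$a[1], r$b[1], rel.tol = 1e-8)$value
  expect_equal(m1[1], direct_m1, tolerance = 1e-5)
})
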