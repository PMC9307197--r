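test_that("subset enumeration has the right counts, order and signs", {
  s2 <- enumerate_subsets(2)
  expect_length(s2, 6)
  expect_identical(s2, list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_length(enumerate_subsets(3), 14)  # 2^4 - 2
  expect_length(enumerate_subsets(5), 62)  # 2^6 - 2
  sizes <- lengths(enumerate_subsets(3))
  expect_true(all(diff(sizes) >= 0))       # size-major ordering
})

test_that("the two-step constructor reproduces the bivariate truncations", {
  # single coordinate half-spaces: identity transform, one finite bound
  t1 <- build_truncation(1, 2)
  expect_equal(t1$T, diag(2))
  expect_equal(t1$c, c(-Inf, -Inf))
  expect_equal(t1$d, c(0, Inf))
  t2 <- build_truncation(2, 2)
  expect_equal(t2$d, c(Inf, 0))

  t12 <- build_truncation(c(1, 2), 2)
  expect_equal(t12$T, diag(2))
  expect_equal(t12$d, c(0, 0))

  t13 <- build_truncation(c(1, 3), 2)
  expect_equal(t13$T, rbind(c(1, 0), c(1, 1)))
  expect_equal(t13$c, c(-Inf, 1))
  expect_equal(t13$d, c(0, Inf))

  t23 <- build_truncation(c(2, 3), 2)
  expect_equal(t23$T, rbind(c(1, 1), c(0, 1)))
  expect_equal(t23$c, c(1, -Inf))
  expect_equal(t23$d, c(Inf, 0))

  # the simplex face alone: dummy row carries infinite bounds
  t3 <- build_truncation(3, 2)
  expect_equal(t3$T[1, ], c(1, 1))
  expect_equal(t3$c[1], 1)
  expect_true(all(is.infinite(t3$c[2]), all(is.infinite(t3$d))))
  expect_equal(qr(t3$T)$rank, 2)

  expect_error(build_truncation(c(1, 2, 3), 2), "between 1 and n")
  expect_error(build_truncation(c(2, 1), 2), "strictly increasing")
})

test_that("constructor output always has full rank and |v| finite bounds", {
  for (n in c(3, 5)) {
    for (v in enumerate_subsets(n)) {
      tr <- build_truncation(v, n)
      expect_true(all(tr$T %in% c(0, 1)))
      expect_equal(qr(tr$T)$rank, n)
      expect_equal(sum(is.finite(tr$c)) + sum(is.finite(tr$d)), length(v))
    }
  }
})

test_that("half-space probabilities match closed forms", {
  p <- gaussian_params(c(0, 0), diag(2))
  expect_equal(phi_v(1, p), 0.5, tolerance = 1e-7)
  expect_equal(phi_v(c(1, 2), p), 0.25, tolerance = 2e-6)
  # P(x1 + x2 > 1) with x1 + x2 ~ N(0, 2)
  expect_equal(phi_v(3, p), 1 - pnorm(1 / sqrt(2)), tolerance = 2e-6)
})

test_that("the alternating sum reproduces the explicit six-term expansion", {
  p <- random_problem(2, seed = 201)
  Z <- compute_Z(p)
  phis <- vapply(list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3)),
                 function(v) phi_v(v, p), numeric(1))
  Z_hand <- 1 - phis[1] - phis[2] - phis[3] + phis[4] + phis[5] + phis[6]
  expect_equal(Z, Z_hand, tolerance = 1e-12)
})

test_that("integral, mean and covariance match the quadrature oracle", {
  for (seed in c(11, 12)) {
    p <- random_problem(2, seed = seed)
    o <- oracle_summary(p)
    s <- estimate_semi_analytical(p)
    expect_equal(s$Z, o$Z, tolerance = 1e-5)
    expect_true(max(abs(s$muT - o$muT)) < 5e-5)
    expect_true(max(abs(s$SigmaT - o$SigmaT)) < 5e-5)
  }
  p3 <- random_problem(3, seed = 13)
  o3 <- oracle_summary(p3)
  s3 <- estimate_semi_analytical(p3)
  expect_equal(s3$Z, o3$Z, tolerance = 1e-5)
  expect_true(max(abs(s3$SigmaT - o3$SigmaT)) < 1e-4)
})

test_that("exchangeable inputs give exchangeable means", {
  p <- gaussian_params(c(0.3, 0.3), matrix(c(0.08, 0.03, 0.03, 0.08), 2))
  ws <- stmnd:::build_workspace(p)
  Z <- compute_Z(p, workspace = ws)
  m <- compute_mean(p, Z, ws)
  expect_equal(m[1], m[2], tolerance = 1e-6)
})

test_that("the truncation becomes inactive in the small-covariance limit", {
  p <- gaussian_params(c(0.3, 0.25), diag(1e-8, 2))
  # the alternating sum lands within floating-point noise of 1, so the
  # clipping path announces itself
  expect_warning(s <- estimate_semi_analytical(p), "clipping")
  expect_equal(s$Z, 1, tolerance = 1e-6)
  expect_lt(max(abs(s$muT - p$mu)), 1e-7)
  expect_lt(max(abs(s$SigmaT - p$sigma)), 1e-9)
})

test_that("summary invariants hold on random problems and the cap is enforced", {
  for (n in 2:4) {
    p <- random_problem(n, seed = 500 + n)
    s <- estimate_semi_analytical(p)
    expect_true(all(unlist(stmnd:::check_summary_invariants(s, tol = 1e-6))))
    phis <- s$diagnostics$Phi_v
    singles <- phis[nchar(names(phis)) == 1]
    for (nm in names(phis)) {
      # measure monotonicity under intersection
      idx <- strsplit(nm, "")[[1]]
      expect_lte(phis[[nm]], min(singles[idx]) + 1e-6)
    }
  }
  p7 <- gaussian_params(rep(0.1, 7), diag(0.01, 7))
  expect_error(estimate_semi_analytical(p7), "cap")
})
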