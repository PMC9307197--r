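test_that("feasible arcs have closed forms in degenerate geometries", {
  p <- gaussian_params(c(0.3, 0.3), diag(0.05, 2))
  # loosen so far that the whole ellipse is feasible
  d_loose <- simplex_domain(p, gamma = 100)
  arcs <- feasible_arcs(c(0.01, 0.01), c(0.02, -0.01), d_loose)
  expect_equal(arcs$total_measure, 2 * pi)
  expect_equal(nrow(arcs$intervals), 1L)

  # single active constraint x >= 0 through the origin: cos(theta) >= 0
  dom <- list(A = matrix(c(1, 0), nrow = 1), c_prime = 0)
  arcs <- feasible_arcs(c(1, 0), c(0, 1), dom)
  expect_equal(arcs$total_measure, pi, tolerance = 1e-12)
  expect_true(arc_contains(arcs, 0.1))
  expect_true(arc_contains(arcs, 2 * pi - 0.1))
  expect_false(arc_contains(arcs, pi))
})

test_that("arc sets agree with a dense-grid feasibility oracle", {
  set.seed(42)
  for (n in c(2, 3, 5)) {
    for (rep in 1:20) {
      p <- random_problem(n, seed = 1000 * n + rep)
      dom <- simplex_domain(p, gamma = runif(1, 0, 0.3))
      x0 <- rep(1 / (2 * n), n)
      y <- x0 - p$mu
      nu <- as.numeric(stmnd:::rmvn_chol(1, rep(0, n), p$L))
      mism <- arc_grid_mismatches(y, nu, dom, n_grid = 2e4)
      # only grid points straddling an arc endpoint may disagree
      expect_lte(mism, 2 * (n + 2))
    }
  }
})

test_that("every chain state is feasible and chains are reproducible", {
  p <- worked_example_params()
  dom <- simplex_domain(p)
  withr::with_seed(9, {
    y <- initial_point(p, dom)
    for (i in 1:2000) {
      y <- ess_step(y, p, dom)
      if (i %% 100 == 0) expect_true(in_domain(y + p$mu, p))
    }
  })
  x1 <- sample_lin_ess(p, dom, n_keep = 50, seed = 4)
  x2 <- sample_lin_ess(p, dom, n_keep = 50, seed = 4)
  expect_identical(x1, x2)
  expect_true(all(in_domain(x1, p)))
})

test_that("the deterministic start point is interior to every loosened domain", {
  for (n in c(2, 5)) {
    p <- random_problem(n, seed = 600 + n)
    dom <- simplex_domain(p)
    x0 <- initial_point(p, dom) + p$mu
    expect_equal(x0, rep(1 / (2 * n), n))
    expect_equal(sum(x0), 0.5)
    for (g in c(0, 0.01, 1)) expect_true(in_domain(x0, p, gamma = g))
  }
})

test_that("thinning keeps every thin-th state of the identical-seed chain", {
  p <- worked_example_params()
  dom <- simplex_domain(p)
  full <- sample_lin_ess(p, dom, n_keep = 6, thin = 1, burn_in = 0, seed = 12)
  half <- sample_lin_ess(p, dom, n_keep = 3, thin = 2, burn_in = 0, seed = 12)
  expect_identical(half, full[c(2, 4, 6), ])
})

test_that("chain moments match rejection sampling within Monte-Carlo error", {
  p <- random_problem(4, seed = 44)
  dom <- simplex_domain(p)
  M <- 5000
  x_ess <- sample_lin_ess(p, dom, n_keep = M, thin = 2, seed = 21)
  r <- estimate_rejection(p, M = M, seed = 22)
  se_ess <- sqrt(vapply(seq_len(4), function(j) stmnd:::batch_var_mean(x_ess[, j]),
                        numeric(1)))
  se <- sqrt(se_ess^2 + r$diagnostics$se_muT^2)
  expect_true(all(abs(colMeans(x_ess) - r$muT) < 4 * se))
})
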