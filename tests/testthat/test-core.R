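test_that("simplex constraint system matches the domain definition", {
  p <- gaussian_params(c(0.3, 0.2), diag(0.01, 2))
  d <- simplex_domain(p, gamma = 0)
  expect_equal(d$A, rbind(c(-1, -1), c(1, 0), c(0, 1)))
  expect_equal(d$c, c(0.5, 0.3, 0.2))
  expect_equal(d$c_prime, d$c)

  d1 <- simplex_domain(p, gamma = 0.1)
  expect_equal(d1$A, d$A)
  expect_equal(d1$c_prime, c(0.6, 0.4, 0.3))

  p3 <- gaussian_params(rep(0, 3), diag(3))
  d3 <- simplex_domain(p3)
  expect_equal(d3$c, c(1, 0, 0, 0))
  x <- c(0.2, 0.3, 0.1)  # interior point of the unit-simplex region
  expect_true(all(d3$A %*% (x - p3$mu) + d3$c > 0))
})

test_that("domain membership is boundary-inclusive and respects loosening", {
  p <- gaussian_params(c(0.3, 0.2), diag(0.01, 2))
  expect_true(in_domain(c(0.2, 0.3), p))
  expect_false(in_domain(c(0.6, 0.6), p, gamma = 0))
  expect_true(in_domain(c(0.6, 0.6), p, gamma = 0.2))
  expect_true(in_domain(c(0, 0), p))
  expect_true(in_domain(c(0.5, 0.5), p))   # on the simplex face
  expect_error(in_domain(c(0.1, 0.1, 0.1), p), "dimension")
})

test_that("parameter validation rejects malformed covariances", {
  expect_error(gaussian_params(c(0, 0), matrix(c(1, 0.5, -0.5, 1), 2)),
               "symmetric")
  expect_error(gaussian_params(c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
  expect_error(gaussian_params(c(0, 0), diag(3)), "matrix")
  # near-symmetric input is symmetrised rather than rejected
  s <- matrix(c(1, 0.5 + 1e-14, 0.5, 1), 2)
  p <- gaussian_params(c(0, 0), s)
  expect_identical(p$sigma, t(p$sigma))
})

test_that("estimate() dispatches, validates settings, and is reproducible", {
  p <- worked_example_params()
  expect_error(estimate(gaussian_params(0.5, matrix(0.01)), "rejection"),
               "n >= 2")
  expect_error(estimate(p, "rejection", list(bogus = 1)), "unknown settings")

  opts <- list(rejection = list(seed = 11, M = 2000),
               gessner = list(seed = 11, M_hdr = 1000),
               semi_analytical = list())
  for (m in names(opts)) {
    s1 <- estimate(p, m, opts[[m]])
    s2 <- estimate(p, m, opts[[m]])
    expect_identical(s1$Z, s2$Z)
    expect_identical(s1$muT, s2$muT)
    expect_identical(s1$SigmaT, s2$SigmaT)
    expect_true(all(unlist(stmnd:::check_summary_invariants(s1, tol = 1e-6))))
  }
})

test_that("estimates are permutation equivariant", {
  p <- random_problem(3, seed = 301)
  perm <- c(3, 1, 2)
  P <- diag(3)[perm, ]
  pp <- gaussian_params(p$mu[perm], p$sigma[perm, perm])

  s <- estimate_semi_analytical(p)
  sp <- estimate_semi_analytical(pp)
  expect_equal(sp$Z, s$Z, tolerance = 1e-8)
  expect_equal(sp$muT, s$muT[perm], tolerance = 1e-7)
  expect_equal(sp$SigmaT, s$SigmaT[perm, perm], tolerance = 1e-7)

  # sampling methods agree under permutation within Monte-Carlo error
  r <- estimate(p, "rejection", list(M = 4000, seed = 5))
  rp <- estimate(pp, "rejection", list(M = 4000, seed = 6))
  se <- sqrt(r$diagnostics$se_muT^2 + rp$diagnostics$se_muT[order(perm)]^2)
  expect_true(all(abs(rp$muT[order(perm)] - r$muT) < 4 * se))
})

test_that("tidy and glance provide the broom-style views", {
  s <- estimate_semi_analytical(worked_example_params())
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1 + 2 + 3)  # Z, two means, covariance upper triangle
  expect_equal(td$estimate[td$quantity == "Z"], s$Z)
  gl <- glance(s)
  expect_equal(gl$n, 2L)
  expect_equal(gl$Z, s$Z)
})

test_that("JSON and CSV round trips preserve the numeric payload", {
  p <- worked_example_params()
  s <- estimate_semi_analytical(p)
  f <- tempfile(fileext = ".json")
  write_stmnd_json(s, f)
  s2 <- read_stmnd_json(f)
  expect_equal(s2$Z, s$Z, tolerance = 1e-14)
  expect_equal(s2$muT, s$muT, tolerance = 1e-14)
  expect_equal(s2$SigmaT, s$SigmaT, tolerance = 1e-14)

  fj <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(mu = p$mu, sigma = p$sigma),
                              digits = NA, auto_unbox = TRUE), fj)
  p2 <- read_gaussian_json(fj)
  expect_equal(p2$mu, p$mu)
  expect_equal(p2$sigma, p$sigma)
  expect_error(read_gaussian_json(tempfile()), "not found")

  fm <- tempfile(fileext = ".csv"); fs <- tempfile(fileext = ".csv")
  write.table(p$mu, fm, row.names = FALSE, col.names = FALSE, sep = ",")
  write.table(p$sigma, fs, row.names = FALSE, col.names = FALSE, sep = ",")
  p3 <- read_gaussian_csv(fm, fs)
  expect_equal(p3$sigma, p$sigma)
})
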