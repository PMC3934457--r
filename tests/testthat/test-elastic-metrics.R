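# TWED / ERP / Euclidean distances: worked examples, oracle equivalence,
# metric axioms, stiffness monotonicity.

test_that("TWED reproduces hand-derived values", {
  # identical inputs cost nothing on any stiffness
  set.seed(1)
  for (i in 1:5) {
    s <- rand_series(sample(2:10, 1))
    expect_identical(twedDistance(s, s, rand_params()), 0)
  }
  # singleton match beats delete-both
  expect_identical(twedDistance(0, 1, elasticParams(lam = 1, nu = 0)), 1)
  expect_identical(twedBruteforce(0, 1, elasticParams(lam = 0, nu = 0)), 1)
  # deleting a duplicated sample costs only lambda
  expect_identical(twedDistance(c(1, 1), 1, elasticParams(lam = 0.5, nu = 0)),
                   0.5)
})

test_that("iterative TWED equals the memoized recursion on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    a <- rand_series(sample(1:6, 1))
    b <- rand_series(sample(1:6, 1))
    p <- rand_params()
    d1 <- twedDistance(a, b, p)
    d2 <- twedBruteforce(a, b, p)
    expect_equal(d1, d2, tolerance = 1e-12)
  }
  expect_error(twedBruteforce(rand_series(9), rand_series(3)), "length <= 8")
})

test_that("ERP boundary, worked values and oracle equivalence", {
  expect_identical(erpDistance(c(1, 2), c(1, 2)), 0)
  # boundary: all-deletion cost against the gap element
  expect_identical(erp_naive(c(1, 2), numeric(0), gap = 0), 3)
  set.seed(43)
  for (i in 1:200) {
    a <- stats::runif(sample(1:6, 1), -2, 2)
    b <- stats::runif(sample(1:6, 1), -2, 2)
    expect_equal(erpDistance(a, b), erp_naive(a, b), tolerance = 1e-12)
  }
})

test_that("euclideanDistance is the plain L2 norm and rejects mismatch", {
  expect_identical(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_identical(euclideanDistance(1:4, 1:4), 0)
  expect_error(euclideanDistance(numeric(150), numeric(149)),
               "equal lengths")
})

test_that("pairwise matrices are symmetric and match direct evaluation", {
  expect_identical(pairwiseDistanceMatrix(list(makeTimeSeries(1:3))),
                   matrix(0, 1, 1))
  two <- list(makeTimeSeries(c(1, 2)), makeTimeSeries(c(1, 2)))
  expect_identical(unname(pairwiseDistanceMatrix(two, "twed")),
                   matrix(0, 2, 2))
  set.seed(44)
  xs <- replicate(5, rand_series(sample(4:9, 1)), simplify = FALSE)
  p <- rand_params()
  M <- pairwiseDistanceMatrix(xs, "twed", p)
  expect_identical(M, t(M))
  expect_identical(diag(M), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5)
    expect_identical(M[i, j], twedDistance(xs[[i]], xs[[j]], p))
})

test_that("TWED and ERP satisfy the metric axioms on random triples", {
  set.seed(45)
  for (i in 1:300) {
    x <- rand_series(sample(3:20, 1))
    y <- rand_series(sample(3:20, 1))
    z <- rand_series(sample(3:20, 1))
    p <- rand_params()
    dxy <- twedDistance(x, y, p); dyx <- twedDistance(y, x, p)
    dxz <- twedDistance(x, z, p); dyz <- twedDistance(y, z, p)
    expect_gte(dxy, 0)
    expect_identical(twedDistance(x, x, p), 0)
    expect_equal(dxy, dyx, tolerance = 1e-12)
    expect_lte(dxz, dxy + dyz + 1e-9)
    exy <- erpDistance(tsValues(x), tsValues(y))
    eyx <- erpDistance(tsValues(y), tsValues(x))
    exz <- erpDistance(tsValues(x), tsValues(z))
    eyz <- erpDistance(tsValues(y), tsValues(z))
    expect_gte(exy, 0)
    expect_equal(exy, eyx, tolerance = 1e-12)
    expect_lte(exz, exy + eyz + 1e-9)
  }
})

test_that("TWED is non-decreasing in both stiffness parameters", {
  set.seed(46)
  lams <- 10^(-5:0); nus <- c(0, 0.25, 0.5, 0.75, 1)
  for (i in 1:10) {
    a <- rand_series(sample(5:12, 1)); b <- rand_series(sample(5:12, 1))
    for (nu in nus) {
      d <- vapply(lams, function(l)
        twedDistance(a, b, elasticParams(l, nu)), numeric(1))
      expect_true(all(diff(d) >= -1e-12))
    }
    for (lam in lams) {
      d <- vapply(nus, function(nu)
        twedDistance(a, b, elasticParams(lam, nu)), numeric(1))
      expect_true(all(diff(d) >= -1e-12))
    }
  }
})

test_that("elastic alignment absorbs smooth time warps", {
  # on a warped copy the optimal TWED path undercuts the rigid diagonal
  # alignment (twice the L1 residual) for the vast majority of warps
  set.seed(99)
  p <- elasticParams(0.01, 0.01)
  wins <- 0L
  for (i in 1:200) {
    cl <- sample(pulseClasses(), 1)
    x <- generatePeriod(cl)@values
    wx <- warpValues(x, eps = stats::rnorm(3, 0, 0.005))
    if (twedDistance(x, wx, p) < 2 * sum(abs(x - wx))) wins <- wins + 1L
  }
  expect_gte(wins, 180L)
})
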