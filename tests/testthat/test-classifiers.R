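# Binary SVM solver, multiclass voting, model serialization, 1NN baselines.

test_that("two-point problem matches the closed-form dual solution", {
  K <- matrix(c(1, 0.5, 0.5, 1), 2)
  m <- trainBinarySVM(K, c(1, -1), C = 1e6)
  # alpha = 1 / (1 - k12) = 2 for both points, b = 0
  expect_equal(sort(m@coefs), c(-2, 2), tolerance = 1e-6)
  expect_equal(m@bias, 0, tolerance = 1e-6)
  expect_equal(decisionValue(m, K[m@supportIndex, 1]), 1, tolerance = 1e-6)
  expect_equal(decisionValue(m, K[m@supportIndex, 2]), -1, tolerance = 1e-6)
})

test_that("solver reaches the brute-force dual optimum on small problems", {
  set.seed(60)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    X <- matrix(stats::rnorm(2 * n), 2)
    K <- exp(-as.matrix(stats::dist(t(X)))^2 / 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(1, 10), 1)
    fit <- trainBinarySVM(K, y, C, tol = 1e-6)
    # (a) no feasible grid point beats the solver beyond tolerance
    grid_best <- svm_dual_oracle(K, y, C, steps = if (n == 4) 40L else 12L)
    expect_gte(fit@objective, grid_best - 1e-5)
    # (b) random feasible perturbation around the solution cannot improve it
    a0 <- numeric(n); a0[fit@supportIndex] <- abs(fit@coefs)
    refined <- svm_dual_refine(K, y, C, a0)
    expect_lte(refined - fit@objective, 1e-5)
  }
})

test_that("KKT structure: feasibility, bound SVs, free-SV margins", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 30
    ds <- small_labelled_set(15, seed = rep)
    kp <- kernelParams(sigma = 20, metric = "euclidean")
    K <- gramEntries(gramMatrix(ds, kp))
    y <- ifelse(as.character(pulseLabels(ds)) == "moderate", 1, -1)
    C <- sample(c(0.1, 1, 100), 1)
    m <- trainBinarySVM(K, y, C)
    a <- abs(m@coefs)
    expect_true(all(a <= C + 1e-8))
    expect_lte(abs(sum(m@coefs)), 1e-6)
    # free support vectors sit on the margin
    free <- which(a > 1e-6 & a < C - 1e-6)
    for (f in free) {
      idx <- m@supportIndex[f]
      val <- decisionValue(m, K[m@supportIndex, idx])
      expect_equal(abs(val), 1, tolerance = 5e-3)
      expect_identical(sign(val), sign(m@coefs[f]))
    }
  }
  # duplicated point with opposite labels and small C: both at the bound
  K2 <- matrix(1, 2, 2)
  m2 <- trainBinarySVM(K2, c(1, -1), C = 0.5)
  expect_equal(abs(m2@coefs), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("decision function evaluates the kernel expansion", {
  # a single zero coefficient makes the expansion vanish: f(z) = b
  m <- new("SVMModel", coefs = 0, bias = 0.7, supportIndex = 1L, cost = 1,
           classPos = "+1", classNeg = "-1", objective = 0)
  expect_identical(decisionValue(m, 0.3), 0.7)
  expect_error(decisionValue(m, c(1, 2)), "does not match")
})

test_that("separable two-class problem is fit exactly at large C", {
  ds <- small_labelled_set(12, seed = 21, classes = c("moderate", "hollow"))
  kp <- kernelParams(sigma = 100, metric = "twed",
                     elastic = elasticParams(0.01, 0.25))
  model <- trainPulseSVM(ds, kp, C = 1e5)
  pred <- predict(model, ds)
  expect_identical(as.character(pred), as.character(pulseLabels(ds)))
})

test_that("one-vs-one multiclass votes correctly and reduces to binary at K=2", {
  ds <- generateDataset(c(moderate = 12, slippery = 10, taut = 12,
                          hollow = 6, unsmooth = 6), seed = 13)
  kp <- kernelParams(sigma = 100, metric = "twed",
                     elastic = elasticParams(0.01, 0.25))
  model <- trainPulseSVM(ds, kp, C = 100)
  expect_identical(length(model@models), 10L)
  pred <- predict(model, ds)
  expect_gte(mean(as.character(pred) == as.character(pulseLabels(ds))), 0.95)
  # determinism
  model2 <- trainPulseSVM(ds, kp, C = 100)
  expect_identical(predict(model2, ds), pred)
  # two classes: multiclass equals the single binary model
  ds2 <- small_labelled_set(8, seed = 22)
  m2 <- trainPulseSVM(ds2, kp, C = 10)
  expect_identical(length(m2@models), 1L)
  bin <- m2@models[[1]]
  K <- gramEntries(gramMatrix(ds2, kp))
  own <- vapply(seq_len(nPeriods(ds2)), function(i) {
    v <- decisionValue(bin, K[bin@supportIndex, i])
    if (v >= 0) bin@classPos else bin@classNeg
  }, character(1))
  expect_identical(as.character(predict(m2, ds2)), own)
})

test_that("model serialization reproduces predictions bit-identically", {
  ds <- small_labelled_set(8, seed = 30, classes = c("slippery", "unsmooth"))
  kp <- kernelParams(sigma = 50, metric = "twed",
                     elastic = elasticParams(0.01, 0.5))
  model <- trainPulseSVM(ds, kp, C = 10)
  f <- tempfile(fileext = ".json")
  writeSVMModel(model, f)
  back <- readSVMModel(f)
  probe <- generateDataset(c(slippery = 3, unsmooth = 3), seed = 31)
  expect_identical(predict(back, probe), predict(model, probe))
  expect_identical(back@models[[1]]@coefs, model@models[[1]]@coefs)
  expect_identical(back@models[[1]]@bias, model@models[[1]]@bias)
  file.remove(f)
})

test_that("1NN classifies by minimal distance with index tie-breaking", {
  ds <- generateDataset(c(moderate = 10, taut = 10), seed = 40)
  # self-queries return their own labels under every metric
  for (metric in c("twed", "erp", "euclidean")) {
    pred <- nnClassify(ds, ds, metric, params = elasticParams(0.01, 0.25))
    expect_identical(as.character(pred), as.character(pulseLabels(ds)))
  }
  # equidistant neighbours: lowest training index wins
  train <- cbind(cleanTemplate("moderate"), cleanTemplate("moderate"))
  z <- cleanTemplate("moderate") + 0.05
  pred <- nnClassify(train, z, "euclidean",
                     labels = c("taut", "hollow"))
  expect_identical(as.character(pred), "taut")
  expect_error(nnClassify(matrix(numeric(0), 150, 0), z, "euclidean",
                          labels = character()), "empty training set")
  # matrix-based oracle agreement on a 50-sample set
  ds50 <- generateDataset(c(moderate = 15, slippery = 10, taut = 15,
                            hollow = 5, unsmooth = 5), seed = 41)
  labs <- as.character(pulseLabels(ds50))
  p <- elasticParams(0.01, 0.25)
  D <- pairwiseDistanceMatrix(ds50, "twed", p)
  probe <- generateDataset(c(moderate = 4, taut = 4), seed = 42)
  direct <- nnClassify(ds50, probe, "twed", params = p)
  for (q in seq_len(nPeriods(probe))) {
    dq <- vapply(seq_len(nPeriods(ds50)), function(i)
      twedDistance(periodMatrix(ds50)[, i], periodMatrix(probe)[, q], p),
      numeric(1))
    expect_identical(as.character(direct[q]), labs[which.min(dq)])
  }
})
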