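# Cross-validation protocol, grid search, confusion/AER bookkeeping.

test_that("stratified folds balance classes and are seed-stable", {
  ds <- generateDataset(seed = 1)
  labs <- pulseLabels(ds)
  folds <- stratifiedKFold(labs, k = 10, seed = 3)
  expect_identical(sort(unlist(folds)), seq_len(247L))
  sizes <- lengths(folds)
  expect_true(all(sizes %in% 24:25))
  for (cl in c("hollow", "unsmooth")) {
    per <- vapply(folds, function(f) sum(labs[f] == cl), integer(1))
    expect_true(all(per %in% 1:2))
  }
  expect_identical(stratifiedKFold(labs, 10, seed = 3), folds)
  expect_error(stratifiedKFold(labs, k = 1), "k must be >= 2")
  expect_error(stratifiedKFold(labs, k = 20), "fewer than k")
  # unstratified folds still partition
  plain <- stratifiedKFold(labs, k = 5, seed = 3, stratify = FALSE)
  expect_identical(sort(unlist(plain)), seq_len(247L))
})

test_that("grid combination tables follow the tuning order and sizes", {
  g <- paramGrid()
  combos <- PulseTWED:::.grid_combos("gtwed-svm", g)
  expect_identical(nrow(combos), 6L * 5L * 7L * 9L)
  # C varies fastest, lambda slowest
  expect_identical(combos$cost[1:2], c(1e-3, 1e-2))
  expect_identical(combos$lam[1], 1e-5)
  expect_identical(combos$lam[nrow(combos)], 1)
  expect_identical(nrow(PulseTWED:::.grid_combos("1nn-ed", g)), 1L)
  expect_identical(nrow(PulseTWED:::.grid_combos("1nn-twed", g)), 30L)
})

test_that("grid search returns the winning point under a constructed gap", {
  ds <- generateDataset(c(moderate = 18, taut = 18), seed = 14)
  # single grid point comes straight back
  g1 <- paramGrid(lam = 0.01, nu = 0.25, sigma = 100, cost = 100)
  sel <- gridSearch(ds, method = "gtwed-svm", grid = g1, seed = 2)
  expect_identical(sel$evaluated, 1L)
  expect_identical(sel$params$sigma, 100)
  # grossly mis-scaled sigma loses to a well-scaled one
  g2 <- paramGrid(lam = 0.01, nu = 0.25, sigma = c(1e-2, 100), cost = 100)
  cache <- new.env(parent = emptyenv())
  sel2 <- gridSearch(ds, method = "gtwed-svm", grid = g2, seed = 2,
                     cache = cache)
  expect_identical(sel2$params$sigma, 100)
  expect_identical(sel2$evaluated, 2L)
  # the distance cache holds exactly one TWED matrix afterwards
  expect_identical(length(ls(cache)), 1L)
})

test_that("nested CV is reproducible and bookkeeping is exact", {
  ds <- generateDataset(c(moderate = 20, slippery = 20, taut = 20),
                        seed = 15)
  grid <- paramGrid(lam = 0.01, nu = c(0, 0.5), sigma = 100, cost = 100)
  r1 <- nestedCV(ds, "1nn-twed", grid, k = 5, seed = 8)
  r2 <- nestedCV(ds, "1nn-twed", grid, k = 5, seed = 8)
  expect_identical(r1, r2)
  cm <- cvConfusion(r1)
  expect_identical(sum(cm), 60L)
  expect_equal(totalAER(r1), 100 * (1 - sum(diag(cm)) / sum(cm)),
               tolerance = 1e-12)
  expect_equal(mean(foldErrors(r1) * lengths(stratifiedKFold(
    pulseLabels(ds), 5, seed = 8))) * 5 / 60,
    totalAER(r1) / 100, tolerance = 1e-12)
  # byte-stable text rendering
  f1 <- tempfile(); f2 <- tempfile()
  writeCVReport(r1, f1); writeCVReport(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  file.remove(f1, f2)
})

test_that("a duplicated dataset with split folds gives 1NN zero error", {
  base <- generateDataset(c(moderate = 10, taut = 10, hollow = 5), seed = 16)
  m <- cbind(periodMatrix(base), periodMatrix(base))
  labs <- rep(as.character(pulseLabels(base)), 2)
  ds <- PulseSet(m, labs)
  n <- nPeriods(base)
  folds <- list(seq_len(n), n + seq_len(n)) # duplicates always apart
  r <- nestedCV(ds, "1nn-ed", k = 2, seed = 1, folds = folds)
  expect_identical(totalAER(r), 0)
  expect_identical(foldErrors(r), c(0, 0))
})

test_that("aerFromConfusion matches published worked examples", {
  tab3 <- matrix(c(719, 63, 17, 1, 0,
                   74, 466, 4, 7, 0,
                   16, 3, 775, 1, 5,
                   7, 12, 3, 136, 2,
                   1, 1, 16, 2, 141),
                 nrow = 5, byrow = TRUE,
                 dimnames = list(pulseClasses(), pulseClasses()))
  out <- aerFromConfusion(tab3, classTotals = c(800, 550, 800, 160, 160))
  expect_equal(out$total, 9.43, tolerance = 0.01)
  expect_equal(unname(out$perClass["moderate"]), 10.12, tolerance = 0.01)
  ident <- diag(c(5, 10, 2, 8, 4))
  out0 <- aerFromConfusion(ident)
  expect_identical(unname(out0$perClass), rep(0, 5))
  expect_identical(out0$total, 0)
  expect_error(aerFromConfusion(diag(c(1, 0))), "zero row total")
  expect_error(aerFromConfusion(matrix(1, 2, 3)), "square")
})

test_that("report rendering includes confusion counts and rates", {
  ds <- generateDataset(c(moderate = 12, taut = 12), seed = 17)
  r <- nestedCV(ds, "1nn-ed", k = 3, seed = 4)
  txt <- renderCVReport(r)
  expect_true(any(grepl("Confusion matrix", txt)))
  expect_true(any(grepl("total", txt)))
  expect_true(any(grepl("fold", txt)))
})
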