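# Independent reference implementations used as test oracles, plus small
# fixture builders. These stay deliberately naive and separate from the
# package's iterative dynamic programs.

# naive memoized ERP recursion (the package's erpDistance is iterative C++)
erp_naive <- function(a, b, gap = 0) {
  m <- length(a); n <- length(b)
  memo <- matrix(NA_real_, m + 1L, n + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L && j == 0L) 0
    else {
      cand <- Inf
      if (i > 0L) cand <- min(cand, rec(i - 1L, j) + abs(a[i] - gap))
      if (j > 0L) cand <- min(cand, rec(i, j - 1L) + abs(b[j] - gap))
      if (i > 0L && j > 0L)
        cand <- min(cand, rec(i - 1L, j - 1L) + abs(a[i] - b[j]))
      cand
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(m, n)
}

# brute-force maximization of the SVM dual over a grid of feasible alpha:
# n-1 free coordinates on a grid, the last fixed by the equality constraint
svm_dual_oracle <- function(K, y, C, steps = 24L) {
  n <- length(y)
  grid <- seq(0, C, length.out = steps + 1L)
  free <- rev(seq_len(n))[-1L] # coordinates 1..n-1 vary, n solved
  best <- -Inf
  combos <- do.call(expand.grid, rep(list(grid), n - 1L))
  for (r in seq_len(nrow(combos))) {
    a <- numeric(n)
    a[seq_len(n - 1L)] <- as.numeric(combos[r, ])
    a[n] <- -sum(a[seq_len(n - 1L)] * y[seq_len(n - 1L)]) / y[n]
    if (a[n] < -1e-12 || a[n] > C + 1e-12) next
    a[n] <- min(max(a[n], 0), C)
    obj <- sum(a) - 0.5 * sum((a * y) %*% K %*% (a * y))
    if (obj > best) best <- obj
  }
  best
}

# local hill-climb refinement of the oracle around a start point, moving
# feasible pairs (keeps the equality constraint exact)
svm_dual_refine <- function(K, y, C, alpha, iters = 2000L) {
  obj <- function(a) sum(a) - 0.5 * drop((a * y) %*% K %*% (a * y))
  best <- obj(alpha)
  n <- length(y)
  step <- C / 8
  for (it in seq_len(iters)) {
    i <- sample.int(n, 1L); j <- sample.int(n, 1L)
    if (i == j) next
    d <- stats::runif(1, -step, step)
    a2 <- alpha
    a2[i] <- a2[i] + d
    a2[j] <- a2[j] - d * y[i] / y[j]
    if (any(a2 < 0) || any(a2 > C)) next
    o2 <- obj(a2)
    if (o2 > best) { alpha <- a2; best <- o2 }
    if (it %% 500L == 0L) step <- step / 2
  }
  best
}

rand_series <- function(len, lo = -2, hi = 2) {
  makeTimeSeries(stats::runif(len, lo, hi))
}

rand_params <- function() {
  elasticParams(lam = sample(10^(-5:0), 1L),
                nu = sample(c(0, 0.25, 0.5, 0.75, 1), 1L))
}

small_labelled_set <- function(n_per = 4L, seed = 7L,
                               classes = c("moderate", "taut")) {
  counts <- stats::setNames(rep(n_per, length(classes)), classes)
  generateDataset(counts, seed = seed)
}
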