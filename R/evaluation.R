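# Evaluation protocol: stratified k-fold CV with an inner tuning split,
# grid search over (lambda, nu, sigma, C), distance-matrix caching, and
# confusion-matrix / average-error-rate bookkeeping.

.cv_methods <- c("gtwed-svm", "gerp-svm", "1nn-twed", "1nn-erp", "1nn-ed")

#' Stratified k-fold partition
#'
#' Splits sample indices into \code{k} disjoint test sets. With
#' stratification (the default) the per-class counts differ by at most one
#' across folds — important here because the rare classes would otherwise
#' vanish from some folds. Deterministic for a fixed seed.
#'
#' @param labels class labels (factor or character), one per sample.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @param stratify if FALSE, plain random splitting is used.
#' @return List of \code{k} integer vectors (test indices).
#' @export
stratifiedKFold <- function(labels, k = 10L, seed = 1L, stratify = TRUE) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2 (k = 1 leaves no held-out data)")
  if (stratify) {
    counts <- table(labels)
    small <- names(counts)[counts < k]
    if (length(small))
      stop(sprintf(
        "class '%s' has %d samples, fewer than k = %d; use a smaller k",
        small[1L], counts[[small[1L]]], k))
  } else if (n < k) {
    stop("fewer samples than folds")
  }
  .with_seed(seed, {
    folds <- vector("list", k)
    if (stratify) {
      offset <- 0L
      for (cl in unique(labels)[order(match(unique(labels), pulseClasses()))]) {
        idx <- sample(which(labels == cl))
        f <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[f == j])
        offset <- (offset + length(idx)) %% k
      }
    } else {
      idx <- sample(n)
      f <- ((seq_len(n) - 1L) %% k) + 1L
      for (j in seq_len(k)) folds[[j]] <- idx[f == j]
    }
    lapply(folds, sort)
  })
}

# grid combinations for a method, in tuning order (lam outer, then nu,
# sigma, C); methods without a parameter carry a single row of NAs
.grid_combos <- function(method, grid) {
  switch(method,
    "gtwed-svm" = expand.grid(cost = grid@cost, sigma = grid@sigma,
                              nu = grid@nu, lam = grid@lam)[, 4:1],
    "gerp-svm" = cbind(lam = NA_real_, nu = NA_real_,
                       expand.grid(cost = grid@cost,
                                   sigma = grid@sigma)[, 2:1]),
    "1nn-twed" = cbind(expand.grid(nu = grid@nu, lam = grid@lam)[, 2:1],
                       sigma = NA_real_, cost = NA_real_),
    "1nn-erp" = ,
    "1nn-ed" = data.frame(lam = NA_real_, nu = NA_real_, sigma = NA_real_,
                          cost = NA_real_),
    stop("unknown method '", method, "'"))
}

# distance-matrix cache over the full dataset, keyed on metric and elastic
# parameters; sigma / C sweeps re-use each matrix
.dist_key <- function(metric, lam, nu) {
  if (metric == "twed") sprintf("twed|%.17g|%.17g", lam, nu) else metric
}

.cached_dist <- function(cache, values, metric, lam = 0, nu = 0, gap = 0) {
  if (is.null(lam) || is.na(lam)) lam <- 0
  if (is.null(nu) || is.na(nu)) nu <- 0
  key <- .dist_key(metric, lam, nu)
  if (!is.null(cache[[key]])) return(cache[[key]])
  D <- pairwiseDistanceMatrix(values, metric = metric,
                              params = elasticParams(max(lam, 0), max(nu, 0)),
                              gap = gap)
  cache[[key]] <- D
  D
}

# error rate of `method` with parameters `pars` trained on trIdx and
# evaluated on teIdx, using the full-dataset distance cache
.eval_split <- function(values, labels, trIdx, teIdx, method, pars, cache,
                        tol = 1e-3) {
  if (method %in% c("1nn-twed", "1nn-erp", "1nn-ed")) {
    metric <- switch(method, "1nn-twed" = "twed", "1nn-erp" = "erp",
                     "euclidean")
    D <- .cached_dist(cache, values, metric, pars$lam, pars$nu)
    pred <- .nn_from_matrix(D, trIdx, teIdx, labels)
  } else {
    metric <- if (method == "gtwed-svm") "twed" else "erp"
    D <- .cached_dist(cache, values, metric, pars$lam, pars$nu)
    sub <- c(trIdx, teIdx)
    Ksub <- exp(-D[sub, sub, drop = FALSE]^2 / (2 * pars$sigma^2))
    ntr <- length(trIdx)
    Ktr <- Ksub[seq_len(ntr), seq_len(ntr), drop = FALSE]
    diag(Ktr) <- 1
    fit <- .train_ovo(Ktr, labels[trIdx], pars$cost, tol = tol)
    Kte <- Ksub[ntr + seq_along(teIdx), seq_len(ntr), drop = FALSE]
    pred <- factor(.predict_ovo(fit$models, fit$classes, Kte),
                   levels = pulseClasses())
  }
  list(pred = pred, error = mean(pred != labels[teIdx]))
}

#' Grid search with an inner tuning split
#'
#' Splits the training indices into T1 (8/9, for fitting) and T2 (1/9, for
#' tuning), stratified and seeded; every grid point is fitted on T1 and
#' scored on T2, and the best accuracy wins. Ties are broken by grid
#' iteration order (lambda outer, then nu, sigma, C, each in listed order).
#' Distance matrices are cached per (metric, lambda, nu), so sigma and C
#' sweeps never re-run the dynamic programs.
#'
#' @param x a \linkS4class{PulseSet} (or 150 x n matrix with \code{labels}).
#' @param trainIdx indices of the training set T.
#' @param method one of \code{"gtwed-svm"}, \code{"gerp-svm"},
#'   \code{"1nn-twed"}, \code{"1nn-erp"}, \code{"1nn-ed"}.
#' @param grid a \linkS4class{ParamGrid}.
#' @param seed RNG seed for the inner split.
#' @param cache environment used as distance-matrix cache (created if NULL).
#' @param labels labels when \code{x} is a matrix.
#' @return A list with \code{params} (named list: lam, nu, sigma, cost),
#'   \code{accuracy} on T2, and \code{evaluated} (number of grid points).
#' @export
gridSearch <- function(x, trainIdx = NULL, method = .cv_methods,
                       grid = paramGrid(), seed = 1L, cache = NULL,
                       labels = NULL) {
  method <- match.arg(method)
  if (is(x, "PulseSet")) {
    labels <- as.character(pulseLabels(x))
    values <- periodMatrix(x)
  } else {
    values <- as.matrix(x)
    labels <- as.character(labels)
  }
  if (is.null(trainIdx)) trainIdx <- seq_len(ncol(values))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (length(unique(labels[trainIdx])) < 2L)
    stop("training set must contain at least 2 classes")

  split_once <- function(s) .with_seed(s, {
    t2 <- integer()
    ok <- TRUE
    for (cl in unique(labels[trainIdx])) {
      idx <- trainIdx[labels[trainIdx] == cl]
      if (length(idx) < 2L) { ok <- FALSE; break }
      n2 <- max(1L, as.integer(round(length(idx) / 9)))
      t2 <- c(t2, sample(idx, n2))
    }
    if (ok) sort(t2) else NULL
  })
  t2 <- split_once(seed)
  if (is.null(t2) ||
      length(unique(labels[setdiff(trainIdx, t2)])) <
        length(unique(labels[trainIdx])))
    t2 <- split_once(seed + 1L)
  if (is.null(t2))
    stop("cannot form a tuning split: a class has fewer than 2 samples")
  t1 <- setdiff(trainIdx, t2)

  combos <- .grid_combos(method, grid)
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    pars <- as.list(combos[r, ])
    res <- .eval_split(values, labels, t1, t2, method, pars, cache)
    acc <- 1 - res$error
    if (is.null(best) || acc > best$accuracy)
      best <- list(params = pars, accuracy = acc)
  }
  best$evaluated <- nrow(combos)
  best
}

#' Nested cross-validation of a pulse classification method
#'
#' For each of \code{k} outer folds, hyperparameters are tuned on the
#' remaining folds via \code{\link{gridSearch}}, the model is refitted on
#' all of them with the selected parameters, and the held-out fold is
#' scored. Per-fold errors and the pooled confusion matrix are accumulated
#' into a \linkS4class{CVReport}; the whole procedure is a pure function of
#' (dataset, method, grid, k, seed).
#'
#' @inheritParams gridSearch
#' @param k number of outer folds (default 10).
#' @param stratify stratify the outer folds? (default TRUE).
#' @param folds optional list of test-index vectors overriding the fold
#'   construction (for controlled experiments).
#' @return A \linkS4class{CVReport}.
#' @export
nestedCV <- function(x, method = .cv_methods, grid = paramGrid(), k = 10L,
                     seed = 1L, stratify = TRUE, cache = NULL,
                     folds = NULL, labels = NULL) {
  method <- match.arg(method)
  if (is(x, "PulseSet")) {
    labels <- as.character(pulseLabels(x))
    values <- periodMatrix(x)
  } else {
    values <- as.matrix(x)
    labels <- as.character(labels)
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(folds))
    folds <- stratifiedKFold(labels, k = k, seed = seed, stratify = stratify)
  classes <- pulseClasses()[pulseClasses() %in% unique(labels)]
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(actual = classes, predicted = classes))
  foldErr <- numeric(length(folds))
  foldPar <- vector("list", length(folds))
  all_idx <- seq_len(ncol(values))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(all_idx, te)
    sel <- tryCatch(
      gridSearch(values, tr, method, grid, seed = seed + f, cache = cache,
                 labels = labels),
      error = function(e) stop(sprintf("fold %d: %s", f,
                                       conditionMessage(e)), call. = FALSE))
    res <- .eval_split(values, labels, tr, te, method, sel$params, cache)
    foldErr[f] <- res$error
    foldPar[[f]] <- sel$params
    for (q in seq_along(te))
      cm[labels[te[q]], as.character(res$pred[q])] <-
        cm[labels[te[q]], as.character(res$pred[q])] + 1L
  }
  aer <- aerFromConfusion(cm)
  new("CVReport", method = method, foldErrors = foldErr,
      foldParams = foldPar, confusion = cm,
      perClassAER = aer$perClass, totalAER = aer$total,
      seed = as.integer(seed),
      protocol = sprintf(
        "%d-fold nested CV (stratified=%s), inner 8/9-1/9 tuning split, grid %d x %d x %d x %d",
        length(folds), stratify, length(grid@lam), length(grid@nu),
        length(grid@sigma), length(grid@cost)))
}

#' Average error rates from a confusion matrix
#'
#' Per-class AER is (row total - diagonal) / row total; total AER is
#' (grand total - trace) / grand total; both in percent. \code{classTotals}
#' overrides the row totals, which is needed to reproduce published tables
#' whose printed rows are internally inconsistent with the stated class
#' sizes.
#'
#' @param cm K x K confusion matrix, rows = actual, columns = predicted.
#' @param classTotals optional per-class sample counts overriding row sums.
#' @return List with \code{perClass} (named numeric, percent) and
#'   \code{total} (percent).
#' @export
#' @examples
#' cm <- diag(c(10, 20))
#' aerFromConfusion(cm)  # 0 everywhere
aerFromConfusion <- function(cm, classTotals = NULL) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion counts must be >= 0")
  totals <- if (is.null(classTotals)) rowSums(cm) else as.numeric(classTotals)
  if (length(totals) != nrow(cm)) stop("classTotals length mismatch")
  if (any(totals == 0)) stop("zero row total: class has no samples")
  perClass <- 100 * (totals - diag(cm)) / totals
  names(perClass) <- rownames(cm)
  grand <- sum(totals)
  total <- 100 * (grand - sum(diag(cm))) / grand
  list(perClass = perClass, total = total)
}
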