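# Kernel SVM on precomputed Gram matrices: binary dual solver wrapper,
# one-vs-one multiclass training and prediction.

#' Train a binary SVM on a precomputed Gram matrix
#'
#' Solves the box-constrained dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'   y_i y_j k(x_i, x_j), \quad 0 \le \alpha_i \le C, \; \sum_i \alpha_i y_i = 0}
#' with an SMO working-set method to the stated KKT tolerance. The bias is
#' the mean of \eqn{y_i - \sum_j \alpha_j y_j k(x_j, x_i)} over free support
#' vectors (falling back to the midpoint of the KKT bounds when none is
#' free), and only samples with \eqn{\alpha_i > 10^{-8}} are kept.
#'
#' @param gram \linkS4class{GramMatrix} or square numeric kernel matrix.
#' @param y labels in \{-1, +1\} (numeric) parallel to the Gram rows.
#' @param C box constraint > 0.
#' @param tol KKT violation tolerance (default 1e-3).
#' @param maxIter iteration cap of the solver.
#' @param classPos,classNeg optional class names attached to +1 / -1.
#' @return An \linkS4class{SVMModel}.
#' @export
#' @examples
#' K <- matrix(c(1, 0.5, 0.5, 1), 2)
#' m <- trainBinarySVM(K, c(1, -1), C = 1e6)  # alpha = (2, 2), b = 0
trainBinarySVM <- function(gram, y, C, tol = 1e-3, maxIter = NULL,
                           classPos = "+1", classNeg = "-1") {
  K <- .gram_entries(gram)
  if (nrow(K) != ncol(K)) stop("Gram matrix must be square")
  y <- as.numeric(y)
  if (length(y) != nrow(K)) stop("labels must parallel the Gram matrix")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be > 0")
  n <- nrow(K)
  if (is.null(maxIter)) maxIter <- max(200000L, 1000L * n)
  fit <- .smo_cpp(K, y, C, tol, as.integer(maxIter))
  if (!fit$converged && fit$gap > 10 * tol)
    stop(sprintf(paste0(
      "SVM solver failed to converge (KKT gap %.3e after %d iterations); ",
      "the Gram matrix may be indefinite - see psdDiagnostics() and ",
      "repairGram()"), fit$gap, fit$iterations))
  alpha <- fit$alpha
  sv <- which(alpha > 1e-8)
  if (!length(sv)) sv <- which.max(alpha)
  # pruning must not break the equality constraint
  if (abs(sum(alpha[sv] * y[sv])) > 1e-6) sv <- which(alpha > 0)
  new("SVMModel", coefs = alpha[sv] * y[sv], bias = fit$bias,
      supportIndex = as.integer(sv), cost = C,
      classPos = classPos, classNeg = classNeg,
      objective = fit$objective)
}

#' Evaluate the SVM decision function
#'
#' Returns \eqn{f(z) = \sum_i \alpha_i y_i k(x_i, z) + b} for a query
#' \code{z}; the sign of the value is the binary prediction.
#'
#' @param model an \linkS4class{SVMModel}.
#' @param kernelRow kernel values \eqn{k(x_i, z)} for every support sample
#'   \eqn{i}, in the order of \code{model@supportIndex}.
#' @return The decision value, a single number.
#' @export
decisionValue <- function(model, kernelRow) {
  stopifnot(is(model, "SVMModel"))
  kernelRow <- as.numeric(kernelRow)
  if (length(kernelRow) != length(model@coefs))
    stop(sprintf("kernel row length %d does not match %d support vectors",
                 length(kernelRow), length(model@coefs)))
  sum(model@coefs * kernelRow) + model@bias
}

# decision values for many queries: Ktq is (queries x train) kernel matrix
# with columns indexed like the training set the model was fit on
.decision_values <- function(model, Ktq) {
  as.numeric(Ktq[, model@supportIndex, drop = FALSE] %*% model@coefs +
               model@bias)
}

.pair_name <- function(a, b) paste(a, b, sep = "|")

# one-vs-one training given a full training Gram and character labels
.train_ovo <- function(K, labels, C, tol = 1e-3) {
  classes <- pulseClasses()[pulseClasses() %in% unique(labels)]
  if (length(classes) < 2L) stop("at least 2 classes are required")
  models <- list()
  for (i in seq_len(length(classes) - 1L)) {
    for (j in seq(i + 1L, length(classes))) {
      ci <- classes[i]; cj <- classes[j]
      idx <- which(labels %in% c(ci, cj))
      ysub <- ifelse(labels[idx] == ci, 1, -1)
      m <- trainBinarySVM(K[idx, idx, drop = FALSE], ysub, C, tol = tol,
                          classPos = ci, classNeg = cj)
      m@supportIndex <- as.integer(idx[m@supportIndex]) # back to global
      models[[.pair_name(ci, cj)]] <- m
    }
  }
  list(models = models, classes = classes)
}

# one-vs-one voting on a (queries x train) kernel matrix; ties go to the
# larger summed |decision value|, then to canonical class order
.predict_ovo <- function(models, classes, Ktq) {
  nq <- nrow(Ktq)
  votes <- matrix(0L, nq, length(classes), dimnames = list(NULL, classes))
  mag <- matrix(0, nq, length(classes), dimnames = list(NULL, classes))
  for (m in models) {
    f <- .decision_values(m, Ktq)
    pos <- f >= 0
    votes[, m@classPos] <- votes[, m@classPos] + as.integer(pos)
    votes[, m@classNeg] <- votes[, m@classNeg] + as.integer(!pos)
    mag[, m@classPos] <- mag[, m@classPos] + abs(f)
    mag[, m@classNeg] <- mag[, m@classNeg] + abs(f)
  }
  out <- character(nq)
  for (q in seq_len(nq)) {
    best <- which(votes[q, ] == max(votes[q, ]))
    if (length(best) > 1L) {
      best <- best[mag[q, best] == max(mag[q, best])]
    }
    out[q] <- classes[best[1L]]
  }
  out
}

#' Train a one-vs-one multiclass pulse SVM
#'
#' Trains one binary SVM per unordered class pair on the pair's sub-Gram
#' and predicts by majority vote; vote ties are broken in favour of the
#' class with the larger summed absolute decision value, then by the fixed
#' class order \code{pulseClasses()}.
#'
#' @param x a \linkS4class{PulseSet}, or a 150 x n matrix with \code{labels}.
#' @param kp shared \linkS4class{KernelParams}.
#' @param C box constraint for every binary problem.
#' @param labels labels when \code{x} is a matrix.
#' @param gram optional precomputed \linkS4class{GramMatrix} (or plain
#'   matrix) over the training samples.
#' @param distCache optional precomputed distance matrix (passed to
#'   \code{\link{gramMatrix}}).
#' @param tol solver KKT tolerance.
#' @return A \linkS4class{PulseSVM}.
#' @export
trainPulseSVM <- function(x, kp = kernelParams(), C = 100, labels = NULL,
                          gram = NULL, distCache = NULL, tol = 1e-3) {
  if (is(x, "PulseSet")) {
    values <- periodMatrix(x)
    labels <- as.character(pulseLabels(x))
  } else {
    values <- as.matrix(x)
    labels <- as.character(labels)
  }
  if (is.null(gram)) gram <- gramMatrix(values, kp, cache = distCache)
  K <- .gram_entries(gram)
  fit <- .train_ovo(K, labels, C, tol = tol)
  new("PulseSVM", models = fit$models, classes = fit$classes,
      kernelParams = kp, cost = C, trainValues = values,
      trainLabels = labels)
}

# kernel rows k(train_i, z_q) for queries (columns of zvals) against the
# stored training samples
.kernel_rows <- function(model, zvals) {
  kp <- model@kernelParams
  tv <- model@trainValues
  n <- ncol(tv); nq <- ncol(zvals)
  K <- matrix(0, nq, n)
  for (q in seq_len(nq)) {
    d <- .cross_distances(tv, zvals[, q], kp@metric, kp@elastic, kp@gap)
    K[q, ] <- exp(-d^2 / (2 * kp@sigma^2))
  }
  K
}

#' Predict pulse classes with a trained PulseSVM
#'
#' @param object a \linkS4class{PulseSVM}.
#' @param newdata a \linkS4class{PulsePeriod}, \linkS4class{PulseSet}, or a
#'   150 x n matrix of periods.
#' @param kernelRows optional precomputed (queries x train) kernel matrix;
#'   when supplied, \code{newdata} is not touched.
#' @return Factor of predicted labels with levels \code{pulseClasses()}.
#' @export
setMethod("predict", "PulseSVM", function(object, newdata = NULL,
                                          kernelRows = NULL) {
  if (is.null(kernelRows)) {
    zvals <- if (is(newdata, "PulseSet")) periodMatrix(newdata)
      else if (is(newdata, "PulsePeriod")) matrix(newdata@values, ncol = 1L)
      else as.matrix(newdata)
    kernelRows <- .kernel_rows(object, zvals)
  }
  factor(.predict_ovo(object@models, object@classes, kernelRows),
         levels = pulseClasses())
})
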