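# 1-nearest-neighbour baselines under the elastic and Euclidean metrics.

#' 1-nearest-neighbour classification
#'
#' Assigns the label of the training sample with minimal distance to the
#' query; distance ties are broken by the smallest training index.
#'
#' @param train a \linkS4class{PulseSet} (or 150 x n matrix with
#'   \code{labels}).
#' @param z query: a \linkS4class{PulsePeriod}, numeric vector, or a matrix
#'   of queries in columns.
#' @param metric \code{"twed"}, \code{"erp"} or \code{"euclidean"}.
#' @param params \linkS4class{ElasticParams} for TWED.
#' @param gap ERP gap element.
#' @param labels labels when \code{train} is a matrix.
#' @return Factor of predicted labels with levels \code{pulseClasses()}.
#' @export
nnClassify <- function(train, z, metric = c("twed", "erp", "euclidean"),
                       params = elasticParams(), gap = 0, labels = NULL) {
  metric <- match.arg(metric)
  if (is(train, "PulseSet")) {
    labels <- as.character(pulseLabels(train))
    train <- periodMatrix(train)
  } else {
    train <- as.matrix(train)
    labels <- as.character(labels)
  }
  if (!ncol(train)) stop("empty training set")
  zm <- if (is(z, "PulsePeriod")) matrix(z@values, ncol = 1L)
    else if (is(z, "PulseSet")) periodMatrix(z)
    else as.matrix(z)
  out <- character(ncol(zm))
  for (q in seq_len(ncol(zm))) {
    d <- .cross_distances(train, zm[, q], metric, params, gap)
    out[q] <- labels[which.min(d)] # which.min takes the lowest index on ties
  }
  factor(out, levels = pulseClasses())
}

# nearest-neighbour prediction from a precomputed full distance matrix
.nn_from_matrix <- function(D, trainIdx, testIdx, labels) {
  pred <- character(length(testIdx))
  for (q in seq_along(testIdx)) {
    d <- D[trainIdx, testIdx[q]]
    pred[q] <- labels[trainIdx[which.min(d)]]
  }
  factor(pred, levels = pulseClasses())
}
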