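# Elastic distances between time series: TWED, ERP, Euclidean baseline.

.as_ts <- function(x) {
  if (is(x, "TimeSeries")) x
  else if (is(x, "PulsePeriod")) makeTimeSeries(x@values)
  else if (is(x, "PulseRecord")) x@series
  else makeTimeSeries(x)
}

#' Time warp edit distance (TWED)
#'
#' Computes the TWED between two time series with an iterative
#' \eqn{(m+1)\times(n+1)} dynamic program. Each cell takes the minimum of
#' three edit operations: delete-in-A with cost
#' \eqn{d(a_i, a_{i-1}) + \nu (t_{a_i} - t_{a_{i-1}}) + \lambda}, match with
#' cost \eqn{d(a_i, b_j) + d(a_{i-1}, b_{j-1}) + \nu (|t_{a_i} - t_{b_j}| +
#' |t_{a_{i-1}} - t_{b_{j-1}}|)}, and the symmetric delete-in-B. Both series
#' are padded with a virtual sample of value 0 at time 0, and the first
#' row/column of the table accumulate repeated deletions from that padded
#' start. With \eqn{\lambda, \nu \ge 0} TWED satisfies all metric axioms,
#' including the triangle inequality.
#'
#' @param a,b \linkS4class{TimeSeries} objects (numeric vectors are accepted
#'   and given timestamps \code{1..n}).
#' @param params an \linkS4class{ElasticParams} with the stiffness pair
#'   (\code{lam}, \code{nu}) and Lp order \code{p}.
#' @return The distance, a single number >= 0.
#' @seealso \code{\link{twedBruteforce}} for the reference recursion,
#'   \code{\link{erpDistance}}, \code{\link{pairwiseDistanceMatrix}}.
#' @export
#' @examples
#' twedDistance(c(0, 1, 2), c(0, 1, 2), elasticParams(1, 0.5))  # 0
#' twedDistance(0, 1, elasticParams(lam = 1, nu = 0))           # 1
twedDistance <- function(a, b, params = elasticParams()) {
  stopifnot(is(params, "ElasticParams"))
  validObject(params)
  a <- .as_ts(a); b <- .as_ts(b)
  .twed_cpp(a@values, a@timestamps, b@values, b@timestamps,
            params@lam, params@nu)
}

#' Reference TWED by memoized recursion
#'
#' A direct memoized transcription of the TWED recursion, independent of the
#' iterative dynamic program in \code{\link{twedDistance}}. It exists for
#' equivalence testing and is guarded to short series.
#'
#' @inheritParams twedDistance
#' @param maxLength guard on either series length (default 8).
#' @return The distance; identical to \code{twedDistance} on valid inputs.
#' @export
twedBruteforce <- function(a, b, params = elasticParams(), maxLength = 8L) {
  stopifnot(is(params, "ElasticParams"))
  a <- .as_ts(a); b <- .as_ts(b)
  m <- length(a@values); n <- length(b@values)
  if (m > maxLength || n > maxLength)
    stop("twedBruteforce is limited to series of length <= ", maxLength)
  av <- c(0, a@values); at <- c(0, a@timestamps)
  bv <- c(0, b@values); bt <- c(0, b@timestamps)
  lam <- params@lam; nu <- params@nu
  memo <- array(NA_real_, dim = c(m + 1L, n + 1L))
  rec <- function(i, j) { # i, j count padded elements consumed (0-based)
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    val <- if (i == 0L && j == 0L) {
      0
    } else {
      cand <- Inf
      if (i > 0L)
        cand <- min(cand, rec(i - 1L, j) + abs(av[i + 1L] - av[i]) +
                      nu * (at[i + 1L] - at[i]) + lam)
      if (i > 0L && j > 0L)
        cand <- min(cand, rec(i - 1L, j - 1L) + abs(av[i + 1L] - bv[j + 1L]) +
                      abs(av[i] - bv[j]) +
                      nu * (abs(at[i + 1L] - bt[j + 1L]) + abs(at[i] - bt[j])))
      if (j > 0L)
        cand <- min(cand, rec(i, j - 1L) + abs(bv[j + 1L] - bv[j]) +
                      nu * (bt[j + 1L] - bt[j]) + lam)
      cand
    }
    memo[i + 1L, j + 1L] <<- val
    val
  }
  rec(m, n)
}

#' Edit distance with real penalty (ERP)
#'
#' Standard ERP dynamic program with a constant gap element: unmatched
#' samples are compared against \code{gap} (default 0), which makes ERP a
#' true metric, unlike dynamic time warping.
#'
#' @inheritParams twedDistance
#' @param gap constant gap element (default 0).
#' @param p Lp order (>= 1); immaterial for scalar samples.
#' @return The distance, a single number >= 0.
#' @export
#' @examples
#' erpDistance(c(1, 2), c(1, 2))  # 0
erpDistance <- function(a, b, gap = 0, p = 1L) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("p must be an integer >= 1")
  a <- .as_ts(a); b <- .as_ts(b)
  .erp_cpp(a@values, b@values, gap)
}

#' Euclidean distance between equal-length series
#'
#' The non-elastic baseline: square root of the sum of squared pointwise
#' differences. Errors on unequal lengths.
#'
#' @inheritParams twedDistance
#' @return The distance, a single number >= 0.
#' @export
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))  # 5
euclideanDistance <- function(a, b) {
  a <- .as_ts(a); b <- .as_ts(b)
  if (length(a@values) != length(b@values))
    stop(sprintf("Euclidean distance requires equal lengths, got %d and %d",
                 length(a@values), length(b@values)))
  sqrt(sum((a@values - b@values)^2))
}

.metric_code <- function(metric) {
  switch(metric, twed = 0L, erp = 1L, euclidean = 2L,
         stop("unknown metric '", metric, "'"))
}

.series_list <- function(xs) {
  if (is(xs, "PulseSet")) {
    m <- periodMatrix(xs)
    list(values = lapply(seq_len(ncol(m)), function(i) m[, i]),
         times = rep(list(as.numeric(seq_len(nrow(m)))), ncol(m)),
         ids = colnames(m))
  } else if (is.matrix(xs)) {
    list(values = lapply(seq_len(ncol(xs)), function(i) xs[, i]),
         times = rep(list(as.numeric(seq_len(nrow(xs)))), ncol(xs)),
         ids = colnames(xs))
  } else {
    tss <- lapply(xs, .as_ts)
    list(values = lapply(tss, function(s) s@values),
         times = lapply(tss, function(s) s@timestamps),
         ids = names(xs))
  }
}

#' Pairwise distance matrix over a collection of series
#'
#' Computes every unordered pair once and mirrors the result; the diagonal
#' is zero.
#'
#' @param xs a list of \linkS4class{TimeSeries} / numeric vectors, a
#'   \linkS4class{PulseSet}, or a numeric matrix with one series per column.
#' @param metric \code{"twed"}, \code{"erp"} or \code{"euclidean"}.
#' @param params \linkS4class{ElasticParams} for TWED.
#' @param gap ERP gap element.
#' @return A symmetric numeric matrix with zero diagonal; dimnames are the
#'   sample identifiers when available.
#' @export
pairwiseDistanceMatrix <- function(xs, metric = c("twed", "erp", "euclidean"),
                                   params = elasticParams(), gap = 0) {
  metric <- match.arg(metric)
  sl <- .series_list(xs)
  if (!length(sl$values)) stop("empty collection")
  if (metric == "euclidean") {
    lens <- lengths(sl$values)
    if (length(unique(lens)) > 1L)
      stop("Euclidean distance requires equal-length series")
  }
  M <- .pairwise_cpp(sl$values, sl$times, .metric_code(metric),
                     params@lam, params@nu, gap)
  if (!is.null(sl$ids)) dimnames(M) <- list(sl$ids, sl$ids)
  M
}

# distances from every series in xs to one query (internal)
.cross_distances <- function(xs, z, metric, params = elasticParams(), gap = 0) {
  sl <- .series_list(xs)
  zt <- .as_ts(z)
  .crossdist_cpp(sl$values, sl$times, zt@values, zt@timestamps,
                 .metric_code(metric), params@lam, params@nu, gap)
}
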