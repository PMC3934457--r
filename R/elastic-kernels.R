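# Gaussian elastic kernels (GTWED, GERP), Gram construction, PSD diagnostics.

.kernel_distance <- function(a, b, kp) {
  switch(kp@metric,
         twed = twedDistance(a, b, kp@elastic),
         erp = erpDistance(a, b, gap = kp@gap, p = kp@elastic@p),
         euclidean = euclideanDistance(a, b))
}

#' Gaussian TWED kernel
#'
#' \eqn{k(A, B) = \exp(-d_{twed}(A, B)^2 / (2\sigma^2))}: the TWED metric
#' embedded in a Gaussian. Values lie in (0, 1], with 1 attained exactly at
#' distance 0. Metricity of TWED is necessary (not sufficient) for this
#' kernel to be positive definite; see \code{\link{psdDiagnostics}}.
#'
#' @param a,b time series (as in \code{\link{twedDistance}}).
#' @param kp a \linkS4class{KernelParams} with \code{metric = "twed"}.
#' @return Kernel value in (0, 1].
#' @export
#' @examples
#' gtwedKernel(c(0, 1), c(0, 1), kernelParams(sigma = 1))  # 1
gtwedKernel <- function(a, b, kp = kernelParams(metric = "twed")) {
  stopifnot(is(kp, "KernelParams"))
  validObject(kp)
  d <- twedDistance(a, b, kp@elastic)
  exp(-d^2 / (2 * kp@sigma^2))
}

#' Gaussian ERP kernel
#'
#' As \code{\link{gtwedKernel}} with the ERP metric in place of TWED.
#'
#' @inheritParams gtwedKernel
#' @return Kernel value in (0, 1].
#' @export
gerpKernel <- function(a, b, kp = kernelParams(metric = "erp")) {
  stopifnot(is(kp, "KernelParams"))
  validObject(kp)
  d <- erpDistance(a, b, gap = kp@gap, p = kp@elastic@p)
  exp(-d^2 / (2 * kp@sigma^2))
}

#' Build a Gram matrix of pairwise kernel values
#'
#' When a pairwise distance matrix for the same elastic parameters is
#' supplied via \code{cache}, kernel values are derived from it without
#' recomputing the dynamic programs, so sweeps over \code{sigma} (and the
#' SVM cost) are cheap.
#'
#' @param xs collection of series (as in
#'   \code{\link{pairwiseDistanceMatrix}}).
#' @param kp \linkS4class{KernelParams}.
#' @param cache optional precomputed distance matrix for \code{xs} under
#'   \code{kp}'s metric and elastic parameters.
#' @return A \linkS4class{GramMatrix}.
#' @export
gramMatrix <- function(xs, kp = kernelParams(), cache = NULL) {
  stopifnot(is(kp, "KernelParams"))
  validObject(kp)
  sl <- .series_list(xs)
  n <- length(sl$values)
  if (!n) stop("empty collection")
  if (is.null(cache)) {
    cache <- pairwiseDistanceMatrix(xs, metric = kp@metric,
                                    params = kp@elastic, gap = kp@gap)
  } else {
    if (!is.matrix(cache) || nrow(cache) != n || ncol(cache) != n)
      stop(sprintf("cache dimension mismatch: expected %d x %d", n, n))
  }
  entries <- exp(-cache^2 / (2 * kp@sigma^2))
  diag(entries) <- 1
  entries <- (entries + t(entries)) / 2
  ids <- if (is.null(sl$ids)) sprintf("s%03d", seq_len(n)) else sl$ids
  dimnames(entries) <- list(ids, ids)
  new("GramMatrix", entries = entries, ids = ids, params = kp)
}

.gram_entries <- function(g) if (is(g, "GramMatrix")) g@entries else as.matrix(g)

#' Positive-definiteness diagnostics for a Gram matrix
#'
#' Reports the smallest eigenvalue of the symmetrized matrix. Gaussian
#' kernels built on a metric are not guaranteed to be positive definite;
#' the SVM dual is convex only when they are, so indefiniteness is reported,
#' never assumed away.
#'
#' @param g a \linkS4class{GramMatrix} or a square numeric matrix.
#' @param tol eigenvalues above \code{-tol} count as numerically
#'   non-negative (default 1e-8, the noise scale of dense eigensolvers on
#'   unit-diagonal matrices).
#' @return A list with \code{min_eigenvalue} and \code{is_psd_within_tol}.
#' @export
psdDiagnostics <- function(g, tol = 1e-8) {
  m <- .gram_entries(g)
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min_ev <- min(ev)
  list(min_eigenvalue = min_ev, is_psd_within_tol = min_ev >= -tol)
}

#' Repair an indefinite Gram matrix
#'
#' \code{mode = "none"} (the default) returns the matrix unchanged, with a
#' warning when the smallest eigenvalue is below -1e-8 — this reproduces the
#' behaviour of training on the elastic Gram as-is. \code{"clip"} zeroes
#' negative eigenvalues and reconstitutes the matrix (diagonal re-normalized
#' to 1). \code{"jitter"} adds a uniform diagonal shift of
#' \code{|min eigenvalue| + tol} and rescales back to unit diagonal.
#'
#' @param g a \linkS4class{GramMatrix}.
#' @param mode one of \code{"none"}, \code{"clip"}, \code{"jitter"}.
#' @param tol spectral floor used by the repair modes (default 1e-10).
#' @return A \linkS4class{GramMatrix}.
#' @export
repairGram <- function(g, mode = c("none", "clip", "jitter"), tol = 1e-10) {
  if (!is.character(mode) || !all(mode %in% c("none", "clip", "jitter")))
    stop("unknown repair mode; use 'none', 'clip' or 'jitter'")
  mode <- match.arg(mode)
  stopifnot(is(g, "GramMatrix"))
  m <- g@entries
  if (mode == "none") {
    dg <- psdDiagnostics(m)
    if (dg$min_eigenvalue < -1e-8)
      warning(sprintf(
        "Gram matrix is indefinite (min eigenvalue %.3e); SVM training may not be convex",
        dg$min_eigenvalue))
    return(g)
  }
  if (mode == "clip") {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    m2 <- e$vectors %*% (lam * t(e$vectors))
  } else { # jitter
    min_ev <- psdDiagnostics(m)$min_eigenvalue
    shift <- abs(min(min_ev, 0)) + tol
    m2 <- m + diag(shift, nrow(m))
  }
  d <- diag(m2)
  if (any(d <= 0)) stop("repair produced a non-positive diagonal")
  s <- 1 / sqrt(d)
  m2 <- m2 * tcrossprod(s)
  m2 <- (m2 + t(m2)) / 2
  diag(m2) <- 1
  dimnames(m2) <- list(g@ids, g@ids)
  new("GramMatrix", entries = m2, ids = g@ids, params = g@params)
}
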