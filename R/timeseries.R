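#' Resample a time series to a fixed length by piecewise-linear interpolation
#'
#' Evaluates the piecewise-linear interpolant of the input at
#' \code{targetLength} uniformly spaced query positions spanning the input
#' time range. The first and last output values equal the input endpoints
#' exactly. This is the 1-D reading of "bilinear" length normalization for
#' single-period waveforms.
#'
#' @param series a \linkS4class{TimeSeries} with at least 2 samples.
#' @param targetLength desired output length (>= 2).
#' @return A \linkS4class{TimeSeries} of length \code{targetLength} whose
#'   timestamps are the query positions.
#' @export
#' @examples
#' resampleLinear(makeTimeSeries(c(0, 2, 0)), 5)
resampleLinear <- function(series, targetLength) {
  stopifnot(is(series, "TimeSeries"))
  targetLength <- as.integer(targetLength)
  if (targetLength < 2L) stop("targetLength must be >= 2")
  n <- length(series@values)
  if (n < 2L) stop("cannot interpolate a singleton series")
  xout <- seq(series@timestamps[1L], series@timestamps[n],
              length.out = targetLength)
  v <- stats::approx(series@timestamps, series@values, xout = xout,
                     method = "linear", ties = "ordered")$y
  v[1L] <- series@values[1L]
  v[targetLength] <- series@values[n]
  makeTimeSeries(v, xout)
}
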