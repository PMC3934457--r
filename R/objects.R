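# Constructors, accessors and show methods for the core S4 classes.

#' Create a validated TimeSeries
#'
#' @param values numeric samples; non-empty and finite.
#' @param timestamps optional strictly increasing sample times; defaults to
#'   the 1-based sample indices \code{1..n}.
#' @return A \linkS4class{TimeSeries}.
#' @export
#' @examples
#' makeTimeSeries(c(1, 2, 3))
makeTimeSeries <- function(values, timestamps = NULL) {
  values <- as.numeric(values)
  if (is.null(timestamps)) timestamps <- seq_along(values)
  new("TimeSeries", values = values, timestamps = as.numeric(timestamps))
}

#' Create a validated PulseRecord
#'
#' @param values numeric samples of the raw record.
#' @param samplingRate sampling frequency in Hz (default 150).
#' @param subjectId optional subject identifier.
#' @return A \linkS4class{PulseRecord}; timestamps are \code{(0:(n-1))/fs}
#'   seconds.
#' @export
pulseRecord <- function(values, samplingRate = 150, subjectId = character()) {
  values <- as.numeric(values)
  ts <- makeTimeSeries(values, (seq_along(values) - 1) / samplingRate)
  new("PulseRecord", series = ts, samplingRate = as.numeric(samplingRate),
      subjectId = as.character(subjectId))
}

#' Create a validated PulsePeriod
#'
#' @param values exactly 150 finite samples.
#' @param label optional class label, one of \code{pulseClasses()}.
#' @return A \linkS4class{PulsePeriod}.
#' @export
pulsePeriod <- function(values, label = character()) {
  new("PulsePeriod", values = as.numeric(values), label = as.character(label))
}

#' Create a PulseSet from a waveform matrix and labels
#'
#' @param values 150 x n numeric matrix (one normalized period per column),
#'   or a list of \linkS4class{PulsePeriod}s (their labels are used when
#'   \code{labels} is missing).
#' @param labels class labels, one per period.
#' @param ids optional period identifiers (column names).
#' @return A \linkS4class{PulseSet}.
#' @export
PulseSet <- function(values, labels = NULL, ids = NULL) {
  if (is.list(values) && !is.matrix(values)) {
    if (is.null(labels))
      labels <- vapply(values, function(p) p@label[1L], character(1))
    values <- vapply(values, function(p) p@values, numeric(150))
  }
  values <- as.matrix(values)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(ncol(values)))
  colnames(values) <- ids
  lab <- factor(as.character(labels), levels = pulseClasses())
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pulse = values),
    colData = S4Vectors::DataFrame(label = lab, row.names = ids))
  new("PulseSet", se)
}

#' Create ElasticParams
#'
#' Defaults are the operating point commonly selected for pulse waveforms
#' (lambda = 0.01, nu = 0.25).
#'
#' @param lam edit penalty lambda >= 0.
#' @param nu time-stamp weight nu >= 0.
#' @param p Lp-norm order (>= 1); immaterial for scalar samples.
#' @return An \linkS4class{ElasticParams}.
#' @export
elasticParams <- function(lam = 0.01, nu = 0.25, p = 1L) {
  new("ElasticParams", lam = as.numeric(lam), nu = as.numeric(nu),
      p = as.integer(p))
}

#' Create KernelParams
#'
#' @param sigma Gaussian bandwidth > 0.
#' @param metric \code{"twed"}, \code{"erp"} or \code{"euclidean"}.
#' @param elastic \linkS4class{ElasticParams} for the TWED metric.
#' @param gap ERP gap element (default 0).
#' @return A \linkS4class{KernelParams}.
#' @export
kernelParams <- function(sigma = 1, metric = c("twed", "erp", "euclidean"),
                         elastic = elasticParams(), gap = 0) {
  metric <- match.arg(metric)
  new("KernelParams", sigma = as.numeric(sigma), metric = metric,
      elastic = elastic, gap = as.numeric(gap))
}

#' Create a PreprocessConfig
#'
#' @param waveletName wavelet name ("db4", "db2" or "haar").
#' @param denoiseLevels denoising decomposition depth.
#' @param baselineLevel baseline-removal decomposition depth.
#' @param minPeriodS minimum period duration in seconds.
#' @param amplitudeNormalize min-range scale periods to [0, 1]?
#' @param targetLength normalized period length.
#' @param boundary wavelet boundary handling ("reflect" or "periodic").
#' @return A \linkS4class{PreprocessConfig}.
#' @export
preprocessConfig <- function(waveletName = "db4", denoiseLevels = 2L,
                             baselineLevel = 7L, minPeriodS = 0.35,
                             amplitudeNormalize = FALSE, targetLength = 150L,
                             boundary = "reflect") {
  new("PreprocessConfig", waveletName = waveletName,
      denoiseLevels = as.integer(denoiseLevels),
      baselineLevel = as.integer(baselineLevel),
      minPeriodS = as.numeric(minPeriodS),
      amplitudeNormalize = isTRUE(amplitudeNormalize),
      targetLength = as.integer(targetLength), boundary = boundary)
}

#' Create a NoiseConfig
#'
#' @param snrDb white-noise SNR in dB (Inf disables white noise).
#' @param powerlineHz powerline frequency, Hz.
#' @param powerlineRel powerline amplitude relative to peak-to-peak range.
#' @param driftHz drift frequency range, Hz.
#' @param driftRel drift amplitude relative to peak-to-peak range.
#' @param periodJitter relative s.d. of period durations.
#' @return A \linkS4class{NoiseConfig}.
#' @export
noiseConfig <- function(snrDb = 25, powerlineHz = 50, powerlineRel = 0.02,
                        driftHz = c(0.2, 0.4), driftRel = 0.3,
                        periodJitter = 0.05) {
  new("NoiseConfig", snrDb = snrDb, powerlineHz = powerlineHz,
      powerlineRel = powerlineRel, driftHz = driftHz, driftRel = driftRel,
      periodJitter = periodJitter)
}

#' Create a ParamGrid
#'
#' @param lam,nu,sigma,cost candidate values; defaults are the standard
#'   tuning grids (see \linkS4class{ParamGrid}).
#' @return A \linkS4class{ParamGrid}.
#' @export
paramGrid <- function(lam = 10^(-5:0), nu = c(0, 0.25, 0.5, 0.75, 1),
                      sigma = 10^(-2:4), cost = 10^(-3:5)) {
  new("ParamGrid", lam = lam, nu = nu, sigma = sigma, cost = cost)
}

# ---- accessors ----

#' @describeIn makeTimeSeries sample values of a TimeSeries.
#' @param x object to access.
#' @export
tsValues <- function(x) {
  if (is(x, "PulseRecord")) x@series@values
  else if (is(x, "PulsePeriod")) x@values
  else x@values
}

#' @describeIn makeTimeSeries timestamps of a TimeSeries.
#' @export
tsTimes <- function(x) {
  if (is(x, "PulseRecord")) x@series@timestamps
  else if (is(x, "PulsePeriod")) seq_along(x@values)
  else x@timestamps
}

#' Accessors for pulse collections
#'
#' \code{periodMatrix} returns the 150 x n waveform matrix of a
#' \linkS4class{PulseSet}; \code{pulseLabels} its label factor;
#' \code{nPeriods} the number of periods; \code{getPeriod} one column as a
#' \linkS4class{PulsePeriod}.
#'
#' @param x a \linkS4class{PulseSet}.
#' @return See individual descriptions.
#' @export
periodMatrix <- function(x) SummarizedExperiment::assay(x, "pulse")

#' @rdname periodMatrix
#' @export
pulseLabels <- function(x) SummarizedExperiment::colData(x)$label

#' @rdname periodMatrix
#' @export
nPeriods <- function(x) ncol(x)

#' @rdname periodMatrix
#' @param i column index.
#' @export
getPeriod <- function(x, i) {
  m <- periodMatrix(x)
  pulsePeriod(m[, i], as.character(pulseLabels(x)[i]))
}

#' @rdname periodMatrix
#' @export
samplingRate <- function(x) x@samplingRate

#' Accessors for OnsetList
#' @param x an \linkS4class{OnsetList}.
#' @return integer vector of 1-based onset sample positions.
#' @export
onsetIndices <- function(x) x@indices

#' Accessors for GramMatrix
#' @param x a \linkS4class{GramMatrix}.
#' @return \code{gramEntries}: the numeric matrix; \code{gramParams}: the
#'   generating \linkS4class{KernelParams}.
#' @export
gramEntries <- function(x) x@entries

#' @rdname gramEntries
#' @export
gramParams <- function(x) x@params

#' Accessors for CVReport
#' @param x a \linkS4class{CVReport}.
#' @return \code{foldErrors}: per-fold error fractions; \code{foldParams}:
#'   selected hyperparameters per fold; \code{cvConfusion}: pooled confusion
#'   matrix; \code{perClassAER}/\code{totalAER}: error rates in percent.
#' @export
foldErrors <- function(x) x@foldErrors

#' @rdname foldErrors
#' @export
foldParams <- function(x) x@foldParams

#' @rdname foldErrors
#' @export
cvConfusion <- function(x) x@confusion

#' @rdname foldErrors
#' @export
perClassAER <- function(x) x@perClassAER

#' @rdname foldErrors
#' @export
totalAER <- function(x) x@totalAER

# ---- show methods ----

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries of length %d, t in [%g, %g], values in [%g, %g]\n",
              length(object@values), object@timestamps[1L],
              object@timestamps[length(object@timestamps)],
              min(object@values), max(object@values)))
})

setMethod("show", "PulseRecord", function(object) {
  cat(sprintf("PulseRecord: %d samples at %g Hz (%.2f s)%s\n",
              length(object@series@values), object@samplingRate,
              length(object@series@values) / object@samplingRate,
              if (length(object@subjectId))
                paste0(", subject ", object@subjectId) else ""))
})

setMethod("show", "PulsePeriod", function(object) {
  cat(sprintf("PulsePeriod: 150 samples%s\n",
              if (length(object@label)) paste0(", label '", object@label, "'")
              else " (unlabelled)"))
})

setMethod("show", "ElasticParams", function(object) {
  cat(sprintf("ElasticParams: lambda = %g, nu = %g, p = %d\n",
              object@lam, object@nu, object@p))
})

setMethod("show", "KernelParams", function(object) {
  cat(sprintf("KernelParams: %s kernel, sigma = %g", object@metric,
              object@sigma))
  if (object@metric == "twed")
    cat(sprintf(" (lambda = %g, nu = %g)", object@elastic@lam,
                object@elastic@nu))
  if (object@metric == "erp") cat(sprintf(" (gap = %g)", object@gap))
  cat("\n")
})

setMethod("show", "GramMatrix", function(object) {
  cat(sprintf("GramMatrix: %d x %d, %s kernel, sigma = %g\n",
              nrow(object@entries), ncol(object@entries),
              object@params@metric, object@params@sigma))
})

setMethod("show", "OnsetList", function(object) {
  cat(sprintf("OnsetList: %d onsets, first at %d, last at %d\n",
              length(object@indices), object@indices[1L],
              object@indices[length(object@indices)]))
})

setMethod("show", "SVMModel", function(object) {
  cat(sprintf(
    "Binary SVMModel (%s vs %s): %d support vectors, C = %g, b = %.6g\n",
    object@classPos, object@classNeg, length(object@supportIndex),
    object@cost, object@bias))
})

setMethod("show", "PulseSVM", function(object) {
  cat(sprintf(
    "PulseSVM: %d classes, %d pairwise models, %s kernel (sigma = %g), C = %g\n",
    length(object@classes), length(object@models),
    object@kernelParams@metric, object@kernelParams@sigma, object@cost))
})

setMethod("show", "CVReport", function(object) {
  cat(renderCVReport(object), sep = "\n")
})
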