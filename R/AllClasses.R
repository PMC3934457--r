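#' The five pulse morphology classes
#'
#' Returns the fixed vocabulary of pulse pattern labels, in canonical order.
#' Every labelled object in the package uses this order for factors,
#' confusion-matrix rows/columns and multiclass tie-breaking.
#'
#' @return Character vector of the five class names.
#' @export
#' @examples
#' pulseClasses()
pulseClasses <- function() c("moderate", "slippery", "taut", "hollow", "unsmooth")

#' TimeSeries: a finite real-valued series with strictly increasing timestamps
#'
#' @slot values numeric samples (pressure, arbitrary units).
#' @slot timestamps numeric sample times; strictly increasing, same length as
#'   \code{values}. Defaults to the 1-based sample index.
#' @exportClass TimeSeries
setClass("TimeSeries",
  representation(values = "numeric", timestamps = "numeric"),
  validity = function(object) {
    v <- object@values; t <- object@timestamps
    if (length(v) < 1L) return("values must be non-empty")
    if (length(v) != length(t)) return("values and timestamps differ in length")
    bad <- which(!is.finite(v))
    if (length(bad)) return(sprintf("non-finite value at index %d", bad[1L]))
    if (any(!is.finite(t))) return("non-finite timestamp")
    if (length(t) > 1L) {
      nd <- which(diff(t) <= 0)
      if (length(nd)) return(sprintf("timestamps non-increasing at index %d", nd[1L] + 1L))
    }
    TRUE
  })

#' PulseRecord: a uniformly sampled raw pulse pressure record
#'
#' @slot series a \linkS4class{TimeSeries} with uniform spacing
#'   \code{1/samplingRate}.
#' @slot samplingRate sampling frequency in Hz (default 150).
#' @slot subjectId optional subject identifier (length 0 or 1).
#' @exportClass PulseRecord
setClass("PulseRecord",
  representation(series = "TimeSeries", samplingRate = "numeric",
                 subjectId = "character"),
  validity = function(object) {
    fs <- object@samplingRate
    if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
      return("samplingRate must be a single positive number")
    t <- object@series@timestamps
    if (length(t) > 1L) {
      dt <- diff(t)
      if (any(abs(dt - 1 / fs) > 1e-9 * (1 / fs)))
        return("timestamps are not uniform with spacing 1/samplingRate")
    }
    if (length(object@subjectId) > 1L) return("subjectId must have length 0 or 1")
    TRUE
  })

#' PulsePeriod: one normalized single-period waveform of 150 samples
#'
#' @slot values exactly 150 finite samples; the implied timestamps are the
#'   integers 1..150.
#' @slot label optional class label (length 0 or 1, one of
#'   \code{pulseClasses()}).
#' @exportClass PulsePeriod
setClass("PulsePeriod",
  representation(values = "numeric", label = "character"),
  validity = function(object) {
    if (length(object@values) != 150L)
      return(sprintf("a pulse period must have exactly 150 samples, got %d",
                     length(object@values)))
    if (any(!is.finite(object@values))) return("non-finite sample value")
    if (length(object@label) > 1L) return("label must have length 0 or 1")
    if (length(object@label) == 1L && !(object@label %in% pulseClasses()))
      return(sprintf("unknown label '%s'; valid labels are: %s",
                     object@label, paste(pulseClasses(), collapse = ", ")))
    TRUE
  })

#' PulseSet: a labelled collection of normalized pulse periods
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: the single assay
#' \code{"pulse"} is a 150 x n matrix (rows = the 150 sample positions of a
#' normalized period, columns = periods) and \code{colData} carries a
#' \code{label} factor with levels \code{pulseClasses()}.
#'
#' @exportClass PulseSet
setClass("PulseSet", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!("pulse" %in% SummarizedExperiment::assayNames(object)))
      return("assay 'pulse' is missing")
    m <- SummarizedExperiment::assay(object, "pulse")
    if (nrow(m) != 150L) return("assay 'pulse' must have 150 rows")
    if (any(!is.finite(m))) return("non-finite sample value in assay 'pulse'")
    cd <- SummarizedExperiment::colData(object)
    if (!("label" %in% colnames(cd))) return("colData column 'label' is missing")
    lab <- cd$label
    if (!is.factor(lab) || !identical(levels(lab), pulseClasses()))
      return("colData 'label' must be a factor with levels pulseClasses()")
    if (anyNA(lab)) return("missing label")
    TRUE
  })

#' ElasticParams: stiffness parameters of the TWED metric
#'
#' @slot lam edit (deletion) penalty lambda, in signal units; >= 0.
#' @slot nu time-stamp weight nu, in signal units per time unit; >= 0.
#' @slot p order of the Lp norm used for sample differences; >= 1. For the
#'   scalar samples used here every Lp norm coincides with the absolute
#'   difference, so \code{p} only matters for future multivariate series.
#' @exportClass ElasticParams
setClass("ElasticParams",
  representation(lam = "numeric", nu = "numeric", p = "integer"),
  prototype(lam = 0.01, nu = 0.25, p = 1L),
  validity = function(object) {
    if (length(object@lam) != 1L || !is.finite(object@lam) || object@lam < 0)
      return("lam must be a single finite number >= 0")
    if (length(object@nu) != 1L || !is.finite(object@nu) || object@nu < 0)
      return("nu must be a single finite number >= 0")
    if (length(object@p) != 1L || is.na(object@p) || object@p < 1L)
      return("p must be a single integer >= 1")
    TRUE
  })

#' KernelParams: parameters of a Gaussian elastic kernel
#'
#' @slot sigma Gaussian bandwidth sigma > 0 (units of the underlying distance).
#' @slot metric one of \code{"twed"}, \code{"erp"}, \code{"euclidean"} (the
#'   last gives the ordinary Gaussian RBF kernel on equal-length series, used
#'   as a positive-definite control).
#' @slot elastic \linkS4class{ElasticParams}, used when \code{metric} is
#'   \code{"twed"}.
#' @slot gap ERP gap element (default 0), used when \code{metric} is
#'   \code{"erp"}.
#' @exportClass KernelParams
setClass("KernelParams",
  representation(sigma = "numeric", metric = "character",
                 elastic = "ElasticParams", gap = "numeric"),
  prototype(sigma = 1, metric = "twed", gap = 0),
  validity = function(object) {
    if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
      return("sigma must be a single finite number > 0")
    if (length(object@metric) != 1L ||
        !(object@metric %in% c("twed", "erp", "euclidean")))
      return("metric must be one of 'twed', 'erp', 'euclidean'")
    if (length(object@gap) != 1L || !is.finite(object@gap))
      return("gap must be a single finite number")
    TRUE
  })

#' GramMatrix: pairwise kernel values with the parameters that generated them
#'
#' @slot entries n x n numeric matrix of kernel values.
#' @slot ids sample identifiers (row/column names).
#' @slot params the \linkS4class{KernelParams} used to build the matrix.
#' @exportClass GramMatrix
setClass("GramMatrix",
  representation(entries = "matrix", ids = "character", params = "KernelParams"),
  validity = function(object) {
    m <- object@entries
    if (nrow(m) != ncol(m)) return("entries must be square")
    if (length(object@ids) != nrow(m)) return("ids length must match dimension")
    if (max(abs(m - t(m))) > 1e-12) return("entries must be symmetric within 1e-12")
    if (max(abs(diag(m) - 1)) > 1e-12) return("diagonal must equal 1 within 1e-12")
    # kernel-built Grams live in (0, 1]; spectrum-repaired ones may dip
    # marginally below 0, hence the small slack
    if (min(m) < -1e-6 || max(m) > 1 + 1e-12)
      return("entries must lie in (0, 1] (within repair tolerance)")
    TRUE
  })

#' OnsetList: detected period onsets within a record
#'
#' @slot indices strictly increasing 1-based sample positions of the period
#'   feet (at least 2 to delimit one period).
#' @exportClass OnsetList
setClass("OnsetList",
  representation(indices = "integer"),
  validity = function(object) {
    i <- object@indices
    if (length(i) < 2L) return("at least 2 onsets are required")
    if (any(diff(i) <= 0L)) return("onsets must be strictly increasing")
    TRUE
  })

#' PreprocessConfig: settings of the raw-record preprocessing chain
#'
#' @slot waveletName wavelet used for denoising and baseline removal
#'   (\code{"db4"} default; \code{"db2"} and \code{"haar"} also available).
#' @slot denoiseLevels decomposition depth for denoising (default 2: at
#'   150 Hz the thresholded bands are roughly [18.75, 75] Hz, above the
#'   waveform's morphological content but covering measurement noise and
#'   50 Hz powerline; deeper thresholding erodes the systolic upstroke).
#' @slot baselineLevel decomposition depth whose approximation is removed as
#'   baseline drift (default 7; at 150 Hz this removes roughly [0, 0.59] Hz,
#'   covering respiration/sensor drift while staying below cardiac
#'   fundamentals at ~0.9-1.7 Hz).
#' @slot minPeriodS refractory period between onsets, seconds (default 0.35).
#' @slot amplitudeNormalize if TRUE, periods are min-range scaled to [0, 1]
#'   after length normalization (default FALSE: amplitude is preserved).
#' @slot targetLength length of the normalized period (default 150).
#' @slot boundary wavelet boundary handling: \code{"reflect"} (default) or
#'   \code{"periodic"}.
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(waveletName = "character", denoiseLevels = "integer",
                 baselineLevel = "integer", minPeriodS = "numeric",
                 amplitudeNormalize = "logical", targetLength = "integer",
                 boundary = "character"),
  prototype(waveletName = "db4", denoiseLevels = 2L, baselineLevel = 7L,
            minPeriodS = 0.35, amplitudeNormalize = FALSE,
            targetLength = 150L, boundary = "reflect"),
  validity = function(object) {
    if (object@denoiseLevels < 1L || object@baselineLevel < 1L)
      return("decomposition levels must be >= 1")
    if (object@minPeriodS <= 0) return("minPeriodS must be > 0")
    if (object@targetLength < 2L) return("targetLength must be >= 2")
    if (!(object@boundary %in% c("reflect", "periodic")))
      return("boundary must be 'reflect' or 'periodic'")
    TRUE
  })

#' NoiseConfig: disturbance model of the synthetic record generator
#'
#' @slot snrDb white measurement noise level as signal-to-noise ratio in dB
#'   (default 25; \code{Inf} disables it).
#' @slot powerlineHz powerline interference frequency (default 50 Hz).
#' @slot powerlineRel powerline amplitude relative to the clean signal's
#'   peak-to-peak range (default 0.02).
#' @slot driftHz frequency range of the sinusoidal baseline drift, Hz
#'   (default c(0.2, 0.4)).
#' @slot driftRel drift amplitude relative to the clean peak-to-peak range
#'   (default 0.3).
#' @slot periodJitter relative standard deviation of period durations
#'   (default 0.05).
#' @exportClass NoiseConfig
setClass("NoiseConfig",
  representation(snrDb = "numeric", powerlineHz = "numeric",
                 powerlineRel = "numeric", driftHz = "numeric",
                 driftRel = "numeric", periodJitter = "numeric"),
  prototype(snrDb = 25, powerlineHz = 50, powerlineRel = 0.02,
            driftHz = c(0.2, 0.4), driftRel = 0.3, periodJitter = 0.05),
  validity = function(object) {
    if (is.na(object@snrDb)) return("snrDb must not be NA")
    if (object@powerlineRel < 0 || object@driftRel < 0 ||
        object@periodJitter < 0)
      return("relative amplitudes must be >= 0")
    if (length(object@driftHz) != 2L || any(object@driftHz <= 0))
      return("driftHz must be a positive range c(lo, hi)")
    TRUE
  })

#' SVMModel: a trained binary kernel SVM on a precomputed Gram matrix
#'
#' @slot coefs support coefficients alpha_i * y_i.
#' @slot bias intercept b of the decision function.
#' @slot supportIndex indices of the support samples into the training set.
#' @slot cost box constraint C.
#' @slot classPos,classNeg class names mapped to +1 / -1.
#' @slot objective attained dual objective value.
#' @exportClass SVMModel
setClass("SVMModel",
  representation(coefs = "numeric", bias = "numeric", supportIndex = "integer",
                 cost = "numeric", classPos = "character",
                 classNeg = "character", objective = "numeric"),
  validity = function(object) {
    if (length(object@coefs) != length(object@supportIndex))
      return("coefs and supportIndex differ in length")
    if (length(object@supportIndex) < 1L)
      return("a trained model must keep at least one support vector")
    if (length(object@cost) != 1L || object@cost <= 0)
      return("cost must be a single number > 0")
    if (any(abs(object@coefs) > object@cost + 1e-8))
      return("every |alpha_i| must be <= C")
    if (abs(sum(object@coefs)) > 1e-6)
      return("sum of alpha_i y_i must vanish within 1e-6")
    TRUE
  })

#' PulseSVM: a one-vs-one multiclass kernel SVM over pulse classes
#'
#' @slot models list of binary \linkS4class{SVMModel}s, one per unordered
#'   class pair, named \code{"<classA>|<classB>"}; support indices refer to
#'   columns of \code{trainValues}.
#' @slot classes classes present at training, in canonical order.
#' @slot kernelParams the \linkS4class{KernelParams} of the shared kernel.
#' @slot cost box constraint C used for every binary problem.
#' @slot trainValues 150 x n matrix of the training periods (needed to
#'   evaluate kernel rows for new samples).
#' @slot trainLabels training labels parallel to \code{trainValues} columns.
#' @exportClass PulseSVM
setClass("PulseSVM",
  representation(models = "list", classes = "character",
                 kernelParams = "KernelParams", cost = "numeric",
                 trainValues = "matrix", trainLabels = "character"),
  validity = function(object) {
    k <- length(object@classes)
    if (length(object@models) != k * (k - 1) / 2)
      return("expected exactly K(K-1)/2 binary models")
    TRUE
  })

#' ParamGrid: hyperparameter grids for tuning
#'
#' Defaults follow the standard tuning protocol for the GTWED-SVM:
#' lambda in 10^(-5..0), nu in \{0, 0.25, 0.5, 0.75, 1\}, sigma in 10^(-2..4)
#' and C in 10^(-3..5).
#'
#' @slot lam candidate edit penalties (lambda).
#' @slot nu candidate time-stamp weights (nu); may contain 0.
#' @slot sigma candidate Gaussian bandwidths.
#' @slot cost candidate SVM box constraints (C).
#' @exportClass ParamGrid
setClass("ParamGrid",
  representation(lam = "numeric", nu = "numeric", sigma = "numeric",
                 cost = "numeric"),
  prototype(lam = 10^(-5:0), nu = c(0, 0.25, 0.5, 0.75, 1),
            sigma = 10^(-2:4), cost = 10^(-3:5)),
  validity = function(object) {
    if (!length(object@lam) || !length(object@nu) || !length(object@sigma) ||
        !length(object@cost))
      return("all grids must be non-empty")
    if (any(object@lam <= 0) || any(object@sigma <= 0) || any(object@cost <= 0))
      return("lam, sigma and cost values must be positive")
    if (any(object@nu < 0)) return("nu values must be >= 0")
    TRUE
  })

#' CVReport: results of the nested cross-validation protocol
#'
#' @slot method evaluated method name.
#' @slot foldErrors per-fold error rates (fractions).
#' @slot foldParams per-fold selected hyperparameters.
#' @slot confusion pooled K x K confusion matrix (rows actual, cols predicted).
#' @slot perClassAER per-class average error rates, percent.
#' @slot totalAER total average error rate, percent.
#' @slot seed seed that reproduces the report.
#' @slot protocol human-readable protocol description.
#' @exportClass CVReport
setClass("CVReport",
  representation(method = "character", foldErrors = "numeric",
                 foldParams = "list", confusion = "matrix",
                 perClassAER = "numeric", totalAER = "numeric",
                 seed = "integer", protocol = "character"),
  validity = function(object) {
    cm <- object@confusion
    if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
    if (any(cm < 0)) return("confusion counts must be >= 0")
    expect <- 100 * (1 - sum(diag(cm)) / sum(cm))
    if (abs(expect - object@totalAER) > 1e-8)
      return("totalAER must equal 100 * (1 - trace/total) exactly")
    TRUE
  })
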