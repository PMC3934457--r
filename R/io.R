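# Plain-text I/O: record CSV, period CSV, distance/Gram TSV, model JSON.
# All formats use '.' decimals, comma or tab delimiters, UTF-8, one record
# per row; numbers are printed with %.17g so read -> write round trips are
# byte-identical.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Read a pulse waveform CSV file
#'
#' Two formats are understood and auto-detected. A \emph{record} file has a
#' \code{time,value} header (one sample per row) preceded by a
#' \code{# fs=<rate>} comment, and yields a \linkS4class{PulseRecord}.
#' A \emph{period} file has one period per row: 150 comma-separated values
#' followed by a label column, and yields a \linkS4class{PulseSet}.
#'
#' @param path file to read.
#' @return A \linkS4class{PulseRecord} or \linkS4class{PulseSet}.
#' @export
readPulseCSV <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  if (any(startsWith(lines, "#")) || startsWith(lines[1L], "time,"))
    .read_record_csv(lines, path)
  else
    .read_period_csv(lines, path)
}

.read_record_csv <- function(lines, path) {
  fs <- 150
  subj <- character()
  comment <- startsWith(lines, "#")
  for (cl in lines[comment]) {
    body <- trimws(sub("^#", "", cl))
    if (grepl("^fs=", body)) fs <- as.numeric(sub("^fs=", "", body))
    if (grepl("^subject=", body)) subj <- sub("^subject=", "", body)
  }
  if (!is.finite(fs) || fs <= 0)
    stop("invalid sampling rate declaration in ", path)
  data_lines <- lines[!comment]
  if (!length(data_lines) || data_lines[1L] != "time,value")
    stop("record CSV must start with a 'time,value' header: ", path)
  data_lines <- data_lines[-1L]
  vals <- numeric(length(data_lines))
  for (i in seq_along(data_lines)) {
    parts <- strsplit(data_lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed row at line %d of %s",
                   which(!comment)[i + 1L], path))
    v <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(v))
      stop(sprintf("non-numeric value at line %d of %s",
                   which(!comment)[i + 1L], path))
    vals[i] <- v
  }
  pulseRecord(vals, samplingRate = fs, subjectId = subj)
}

.read_period_csv <- function(lines, path) {
  vals <- matrix(0, nrow = 150L, ncol = length(lines))
  labs <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) != 151L)
      stop(sprintf("line %d of %s: expected 150 samples plus a label, got %d fields",
                   i, path, length(parts)))
    v <- suppressWarnings(as.numeric(parts[1:150]))
    if (anyNA(v)) stop(sprintf("line %d of %s: non-numeric sample", i, path))
    lab <- parts[151L]
    if (!(lab %in% pulseClasses()))
      stop(sprintf("line %d of %s: unknown label '%s'; valid labels are: %s",
                   i, path, lab, paste(pulseClasses(), collapse = ", ")))
    vals[, i] <- v
    labs[i] <- lab
  }
  PulseSet(vals, labs)
}

#' Write pulse waveforms to CSV
#'
#' Writes the formats read back by \code{\link{readPulseCSV}}; a write/read
#' cycle reproduces all values exactly.
#'
#' @param x a \linkS4class{PulseRecord} or \linkS4class{PulseSet}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
setGeneric("writePulseCSV", function(x, path) standardGeneric("writePulseCSV"))

#' @rdname writePulseCSV
#' @export
setMethod("writePulseCSV", "PulseRecord", function(x, path) {
  lines <- c(sprintf("# fs=%s", .fmt_num(x@samplingRate)),
             if (length(x@subjectId)) sprintf("# subject=%s", x@subjectId),
             "time,value",
             paste(.fmt_num(x@series@timestamps), .fmt_num(x@series@values),
                   sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
})

#' @rdname writePulseCSV
#' @export
setMethod("writePulseCSV", "PulseSet", function(x, path) {
  m <- periodMatrix(x)
  labs <- as.character(pulseLabels(x))
  lines <- vapply(seq_len(ncol(m)), function(i) {
    paste(c(.fmt_num(m[, i]), labs[i]), collapse = ",")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
})

#' Write and read square matrices as TSV
#'
#' Distance and Gram matrices are written in full (not triangular) with a
#' header row of sample identifiers; Gram files carry the generating kernel
#' parameters in comment lines.
#'
#' @param m numeric matrix or \linkS4class{GramMatrix}.
#' @param path destination file.
#' @param ids sample identifiers; defaults to the matrix dimnames.
#' @return \code{path}, invisibly (writers); the matrix (readers).
#' @export
writeMatrixTSV <- function(m, path, ids = NULL) {
  comments <- character()
  if (is(m, "GramMatrix")) {
    p <- m@params
    comments <- sprintf(
      "# gram metric=%s sigma=%s lam=%s nu=%s p=%d gap=%s",
      p@metric, .fmt_num(p@sigma), .fmt_num(p@elastic@lam),
      .fmt_num(p@elastic@nu), p@elastic@p, .fmt_num(p@gap))
    ids <- m@ids
    m <- m@entries
  }
  if (is.null(ids)) ids <- colnames(m)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(ncol(m)))
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(.fmt_num(m[i, ]), collapse = "\t"), character(1))
  writeLines(c(comments, paste(ids, collapse = "\t"), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  ids <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  m <- do.call(rbind, lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])))
  dimnames(m) <- list(ids, ids)
  m
}

#' Serialize a trained multiclass SVM as JSON
#'
#' The file stores kernel parameters, class list, and per-pair support
#' indices, coefficients and bias at full precision, together with the
#' training waveforms, so a reloaded model reproduces predictions
#' bit-identically.
#'
#' @param model a \linkS4class{PulseSVM}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeSVMModel <- function(model, path) {
  kp <- model@kernelParams
  obj <- list(
    classes = model@classes,
    cost = model@cost,
    kernel = list(metric = kp@metric, sigma = kp@sigma,
                  lam = kp@elastic@lam, nu = kp@elastic@nu,
                  p = kp@elastic@p, gap = kp@gap),
    trainLabels = model@trainLabels,
    trainValues = as.list(as.numeric(model@trainValues)),
    trainRows = nrow(model@trainValues),
    models = lapply(seq_along(model@models), function(i) {
      m <- model@models[[i]]
      list(pair = names(model@models)[i], classPos = m@classPos,
           classNeg = m@classNeg,
           supportIndex = as.list(m@supportIndex),
           coefs = as.list(m@coefs),
           bias = m@bias, objective = m@objective)
    })
  )
  # I(17) = 17 *significant* digits: doubles survive the round trip exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname writeSVMModel
#' @return \code{readSVMModel}: the reconstructed \linkS4class{PulseSVM}.
#' @export
readSVMModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  kp <- kernelParams(sigma = obj$kernel$sigma, metric = obj$kernel$metric,
                     elastic = elasticParams(obj$kernel$lam, obj$kernel$nu,
                                             obj$kernel$p),
                     gap = obj$kernel$gap)
  models <- lapply(obj$models, function(m)
    new("SVMModel",
        coefs = vapply(m$coefs, as.numeric, numeric(1)),
        bias = as.numeric(m$bias),
        supportIndex = vapply(m$supportIndex, as.integer, integer(1)),
        cost = as.numeric(obj$cost),
        classPos = as.character(m$classPos),
        classNeg = as.character(m$classNeg),
        objective = as.numeric(m$objective)))
  names(models) <- vapply(obj$models, function(m) m$pair, character(1))
  tv <- matrix(vapply(obj$trainValues, as.numeric, numeric(1)),
               nrow = as.integer(obj$trainRows))
  new("PulseSVM", models = models, classes = unlist(obj$classes),
      kernelParams = kp, cost = as.numeric(obj$cost),
      trainValues = tv,
      trainLabels = unlist(obj$trainLabels))
}
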