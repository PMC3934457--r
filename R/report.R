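# Text rendering of cross-validation reports.

.fmt_pct <- function(x) formatC(round(x, 2), format = "f", digits = 2)

#' Render a CVReport as text tables
#'
#' Produces the confusion matrix (rows = actual class, columns = predicted)
#' and the per-class / total average error rates, percentages rounded to two
#' decimals (round-half-even). Note that when re-rendering published tables
#' whose rows disagree with the stated class sizes, per-class rates computed
#' from row sums will differ from the printed ones; see
#' \code{\link{aerFromConfusion}}'s \code{classTotals}.
#'
#' @param report a \linkS4class{CVReport}.
#' @return Character vector of lines.
#' @export
renderCVReport <- function(report) {
  stopifnot(is(report, "CVReport"))
  cm <- report@confusion
  classes <- rownames(cm)
  wide <- max(nchar(classes), 9L) + 2L
  pad <- function(s) formatC(s, width = wide)
  lines <- c(
    sprintf("CVReport: %s (seed %d)", report@method, report@seed),
    report@protocol,
    sprintf("Per-fold error rates: %s",
            paste(.fmt_pct(100 * report@foldErrors), collapse = " ")),
    "",
    "Confusion matrix (rows = actual, columns = predicted):",
    paste0(pad(""), paste(pad(classes), collapse = "")))
  for (i in seq_along(classes))
    lines <- c(lines, paste0(pad(classes[i]),
                             paste(pad(as.character(cm[i, ])), collapse = "")))
  lines <- c(lines, "", "Average error rates (%):")
  for (i in seq_along(classes))
    lines <- c(lines, sprintf("  %-10s %s", classes[i],
                              .fmt_pct(report@perClassAER[i])))
  lines <- c(lines, sprintf("  %-10s %s", "total", .fmt_pct(report@totalAER)))
  sel <- vapply(report@foldParams, function(p) {
    on <- !vapply(p, function(v) is.null(v) || is.na(v), logical(1))
    if (!any(on)) return("-")
    paste(sprintf("%s=%g", names(p)[on], unlist(p[on])), collapse = ", ")
  }, character(1))
  c(lines, "", "Selected parameters per fold:",
    sprintf("  fold %2d: %s", seq_along(sel), sel))
}

#' @rdname renderCVReport
#' @param path destination file.
#' @return \code{writeCVReport}: \code{path}, invisibly.
#' @export
writeCVReport <- function(report, path) {
  writeLines(renderCVReport(report), path, useBytes = TRUE)
  invisible(path)
}
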