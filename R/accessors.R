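#' Accessors for TData
#'
#' @param x A [TData-class] object.
#' @return \code{periodLength}: integer observation-period length T.
#' @examples
#' td <- TData(list(a = c(3L, 9L), b = 5L))
#' periodLength(td)
#' eventLabels(td)
#' seriesPoints(td, "a")
#' @export
periodLength <- function(x) x@period

#' @rdname periodLength
#' @return \code{eventLabels}: character vector of event-type labels.
#' @export
eventLabels <- function(x) names(x@series)

#' @rdname periodLength
#' @param label Event-type label.
#' @return \code{seriesPoints}: integer vector of occurrence times.
#' @export
seriesPoints <- function(x, label) {
  if (!label %in% names(x@series))
    stop("unknown event-type '", label, "'; known: ",
         paste(names(x@series), collapse = ", "))
  x@series[[label]]
}

#' @rdname periodLength
#' @return \code{sampleBoundaries}: integer vector of sample end times.
#' @export
sampleBoundaries <- function(x) x@sampleBoundaries

#' @rdname periodLength
#' @return \code{nEvents}: total number of occurrence points.
#' @export
nEvents <- function(x) sum(lengths(x@series))

#' Accessors for TPattern
#'
#' @param x A [TPattern-class] object.
#' @return \code{patternTerminals}: character vector of terminal labels in
#'   temporal order.
#' @export
patternTerminals <- function(x) x@terminals

#' @rdname patternTerminals
#' @return \code{patternLength}: number of terminals m.
#' @export
patternLength <- function(x) length(x@terminals)

#' @rdname patternTerminals
#' @return \code{patternLevel}: depth of the binary construction tree.
#' @export
patternLevel <- function(x) x@level

#' @rdname patternTerminals
#' @return \code{occurrences}: integer matrix (start, end), one row per
#'   occurrence.
#' @export
occurrences <- function(x) x@occurrences

#' @rdname patternTerminals
#' @return \code{nOccurrences}: number of occurrences n.
#' @export
nOccurrences <- function(x) nrow(x@occurrences)

#' @rdname patternTerminals
#' @return \code{isBurst}: logical, whether the pattern is a univariate
#'   T-burst.
#' @export
isBurst <- function(x) x@burst

#' @rdname patternTerminals
#' @return \code{criticalIntervals}: data.frame of per-node critical
#'   intervals (pre-order over internal nodes) with columns \code{d1},
#'   \code{d2}, \code{pValue}, \code{nHits}.
#' @export
criticalIntervals <- function(x) {
  walk <- function(p) {
    if (is.character(p)) return(NULL)
    rbind(data.frame(d1 = p@ci@d1, d2 = p@ci@d2,
                     pValue = p@ci@pValue, nHits = p@ci@nHits),
          walk(p@left), walk(p@right))
  }
  walk(x)
}

#' @rdname patternTerminals
#' @return \code{maxNodeP}: largest per-node p-value in the tree (the
#'   weakest link of the construction).
#' @export
maxNodeP <- function(x) max(criticalIntervals(x)$pValue)

setMethod("show", "TData", function(object) {
  cat(sprintf("TData: %d series, %d points, T = %d, %d sample(s)\n",
              length(object@series), nEvents(object), object@period,
              length(object@sampleBoundaries)))
  labs <- head(eventLabels(object), 8L)
  for (lab in labs)
    cat(sprintf("  %s: %d points\n", lab, length(object@series[[lab]])))
  if (length(object@series) > 8L)
    cat(sprintf("  ... and %d more series\n", length(object@series) - 8L))
})

setMethod("show", "CriticalInterval", function(object) {
  cat(sprintf("CriticalInterval [%d, %d]  nHits = %d  p = %.4g\n",
              object@d1, object@d2, object@nHits, object@pValue))
})

patternString <- function(p) {
  fmt <- function(x) {
    if (is.character(x)) return(x)
    sprintf("(%s [%d,%d] %s)", fmt(x@left), x@ci@d1, x@ci@d2, fmt(x@right))
  }
  fmt(p)
}

setMethod("show", "TPattern", function(object) {
  kind <- if (object@burst) "T-burst" else "T-pattern"
  cat(sprintf("%s  m = %d  n = %d  level = %d\n  %s\n", kind,
              patternLength(object), nOccurrences(object),
              patternLevel(object), patternString(object)))
})

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf(
    "DetectionParams: alpha = %g, nMin = %d, dMax = %s, maxLevels = %d, maxLength = %d, mode = %s\n",
    object@alpha, object@nMin,
    if (is.na(object@dMax)) "T-1" else as.character(object@dMax),
    object@maxLevels, object@maxLength, object@mode))
})

setMethod("show", "MonteCarloResult", function(object) {
  cat(sprintf("MonteCarloResult (%s, %d randomizations)\n",
              object@method, object@nRandomizations))
  print(as.data.frame(object))
})

#' @describeIn MonteCarloResult-class Tabular view with columns
#'   \code{length}, \code{observed}, \code{mean}, \code{sd}.
#' @param x A \code{MonteCarloResult}.
#' @param row.names,optional,... Passed through (unused).
#' @export
as.data.frame.MonteCarloResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(length = x@lengths, observed = x@observed,
             mean = x@surrogateMean, sd = x@surrogateSd)
}
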