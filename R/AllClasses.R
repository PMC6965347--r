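#' @import methods
#' @importFrom stats pbinom runif sd setNames
#' @importFrom utils head tail
#' @useDynLib tpattern, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' TData: time-stamped categorical event-point series
#'
#' A \code{TData} object holds one or more samples of discrete occurrence
#' point series over a continuous observation period \code{[1, T]}. Each
#' series records the occurrence times (positive integers, discrete time
#' units) of one event-type. Multi-sample data are represented as a single
#' concatenated axis with recorded sample boundaries.
#'
#' @slot period Integer scalar, observation-period length T (time units).
#' @slot series Named list of strictly increasing integer vectors; one
#'   element per event-type, named by its label.
#' @slot sampleBoundaries Sorted integer vector of sample end times; the
#'   last element equals \code{period}. Single-sample data has one element.
#'
#' @seealso [readTData()], [sequenceToTData()], [concatenateSamples()]
#' @export
setClass("TData", representation(
  period = "integer",
  series = "list",
  sampleBoundaries = "integer"
))

setValidity("TData", function(object) {
  msg <- character()
  if (length(object@period) != 1L || is.na(object@period) || object@period < 1L)
    msg <- c(msg, "period must be a single integer >= 1")
  labs <- names(object@series)
  if (length(object@series) && (is.null(labs) || any(labs == "") || anyDuplicated(labs)))
    msg <- c(msg, "series must be uniquely named by non-empty labels")
  for (lab in labs) {
    p <- object@series[[lab]]
    if (!is.integer(p))
      msg <- c(msg, sprintf("series '%s': points must be integer", lab))
    else {
      if (length(p) && (any(is.na(p)) || p[1L] < 1L || p[length(p)] > object@period))
        msg <- c(msg, sprintf("series '%s': points outside [1, T]", lab))
      if (is.unsorted(p, strictly = TRUE))
        msg <- c(msg, sprintf("series '%s': points must be strictly increasing", lab))
    }
  }
  b <- object@sampleBoundaries
  if (!length(b) || is.unsorted(b, strictly = TRUE) || b[length(b)] != object@period ||
      b[1L] < 1L)
    msg <- c(msg, "sampleBoundaries must be strictly increasing and end at period")
  if (length(msg)) msg else TRUE
})

#' Construct a TData object
#'
#' @param series Named list of integer occurrence-time vectors (one per
#'   event-type label). Unsorted vectors are sorted; duplicated times within
#'   a series are an error (they indicate coding errors in the source data).
#' @param period Observation-period length T. Defaults to the maximum
#'   observed time.
#' @param sampleBoundaries Integer vector of sample end times; defaults to
#'   a single sample covering \code{[1, period]}.
#' @return A [TData-class] object.
#' @examples
#' td <- TData(list(a = c(3L, 9L), b = 5L))
#' periodLength(td)
#' @export
TData <- function(series = list(), period = NULL, sampleBoundaries = NULL) {
  series <- lapply(series, function(p) {
    p <- as.integer(p)
    if (anyDuplicated(p))
      stop("duplicate occurrence times within a series: ",
           paste(unique(p[duplicated(p)]), collapse = ", "))
    sort(p)
  })
  if (is.null(period)) {
    mx <- if (length(series)) suppressWarnings(max(vapply(series, function(p)
      if (length(p)) max(p) else 0L, integer(1)))) else 0L
    period <- max(mx, 1L)
  }
  period <- as.integer(period)
  if (is.null(sampleBoundaries)) sampleBoundaries <- period
  new("TData", period = period, series = series,
      sampleBoundaries = as.integer(sampleBoundaries))
}

#' CriticalInterval: the glue relation between two series
#'
#' The interval \code{[d1, d2]} (discrete time units, \code{0 <= d1 <= d2})
#' within which occurrences of a right component follow occurrences of a
#' left component significantly more often than expected under independent
#' random placement, together with the attained tail probability and hit
#' count.
#'
#' @slot d1,d2 Integer interval endpoints, \code{0 <= d1 <= d2}.
#' @slot pValue Exact upper-tail probability of observing at least
#'   \code{nHits} windows containing a right point under the null.
#' @slot nHits Number of left points with at least one right point inside
#'   their window.
#' @export
setClass("CriticalInterval", representation(
  d1 = "integer", d2 = "integer", pValue = "numeric", nHits = "integer"
))

setValidity("CriticalInterval", function(object) {
  msg <- character()
  if (object@d1 < 0L || object@d2 < object@d1)
    msg <- c(msg, "need 0 <= d1 <= d2")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (object@nHits < 0L) msg <- c(msg, "nHits must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname CriticalInterval-class
#' @param d1,d2 Interval endpoints.
#' @param pValue Attained tail probability.
#' @param nHits Hit count.
#' @export
CriticalInterval <- function(d1, d2, pValue = 1, nHits = 0L)
  new("CriticalInterval", d1 = as.integer(d1), d2 = as.integer(d2),
      pValue = as.numeric(pValue), nHits = as.integer(nHits))

#' DetectionParams: search parameters for T-pattern detection
#'
#' @slot alpha Significance level for each critical-interval test
#'   (default 0.005, the conventional default of this method family; the
#'   level is a user decision, not auto-detected).
#' @slot nMin Minimum number of pattern occurrences (default 3; hard floor
#'   2 in general mode). Burst runs always need at least 2 points.
#' @slot dMax Maximum interval end considered; \code{NA} means \code{T - 1}.
#' @slot maxLevels Cap on bottom-up construction passes (default 10).
#' @slot maxLength Cap on the number of terminals m (default 10).
#' @slot mode One of \code{"general"}, \code{"burst"} (univariate
#'   \code{[0, d2]} fast intervals) or \code{"fixed11"} (critical interval
#'   fixed to \code{[1, 1]}, the sequence/substring mode).
#' @export
setClass("DetectionParams", representation(
  alpha = "numeric", nMin = "integer", dMax = "integer",
  maxLevels = "integer", maxLength = "integer", mode = "character"
))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@nMin < 2L) msg <- c(msg, "nMin must be >= 2")
  if (!is.na(object@dMax) && object@dMax < 0L) msg <- c(msg, "dMax must be >= 0")
  if (object@maxLevels < 1L || object@maxLength < 2L)
    msg <- c(msg, "maxLevels >= 1 and maxLength >= 2 required")
  if (!object@mode %in% c("general", "burst", "fixed11"))
    msg <- c(msg, "mode must be general, burst or fixed11")
  if (length(msg)) msg else TRUE
})

#' @rdname DetectionParams-class
#' @param alpha,nMin,dMax,maxLevels,maxLength,mode See slot documentation.
#' @examples
#' detectionParams()          # defaults: alpha 0.005, nMin 3
#' detectionParams(mode = "fixed11", maxLength = 30)
#' @export
detectionParams <- function(alpha = 0.005, nMin = 3, dMax = NA,
                            maxLevels = 10, maxLength = 10,
                            mode = c("general", "burst", "fixed11")) {
  mode <- match.arg(mode)
  new("DetectionParams", alpha = as.numeric(alpha), nMin = as.integer(nMin),
      dMax = as.integer(dMax), maxLevels = as.integer(maxLevels),
      maxLength = as.integer(maxLength), mode = mode)
}

#' TPattern: a detected hierarchical temporal pattern
#'
#' A binary tree whose terminals are event-type labels and whose internal
#' nodes each carry a [CriticalInterval-class] relating the left part's end
#' to the right part's start, together with the list of dated occurrences
#' (start, end) in the data. Burst patterns (univariate dense runs) carry
#' the same structure with both children equal to the series label and
#' occurrences spanning each maximal run.
#'
#' @slot left,right Either a character label (terminal) or a nested
#'   \code{TPattern}.
#' @slot ci The [CriticalInterval-class] of the root node.
#' @slot occurrences Integer matrix with columns \code{start}, \code{end};
#'   one row per occurrence, sorted by start.
#' @slot terminals Character vector of terminal labels in order (cached).
#' @slot level Tree depth (terminals have depth 0).
#' @slot burst Logical; \code{TRUE} for univariate T-bursts.
#' @slot leftMap,rightMap Integer vectors parallel to the occurrence rows:
#'   for each occurrence, the row of the left (right) child's occurrence
#'   list (for terminal children, the index into the series' point vector)
#'   that realizes it. These let an independent verifier re-derive every
#'   terminal time and every node-level gap of every occurrence from raw
#'   data.
#' @export
setClass("TPattern", representation(
  left = "ANY", right = "ANY", ci = "CriticalInterval",
  occurrences = "matrix", terminals = "character",
  level = "integer", burst = "logical",
  leftMap = "integer", rightMap = "integer"
))

setValidity("TPattern", function(object) {
  msg <- character()
  for (child in list(object@left, object@right))
    if (!is.character(child) && !is(child, "TPattern"))
      msg <- c(msg, "children must be labels or TPattern objects")
  occ <- object@occurrences
  if (ncol(occ) != 2L)
    msg <- c(msg, "occurrences must have two columns (start, end)")
  else {
    if (nrow(occ) && is.unsorted(occ[, 1L]))
      msg <- c(msg, "occurrences must be sorted by start")
    if (nrow(occ) && any(occ[, 2L] < occ[, 1L]))
      msg <- c(msg, "occurrence end before start")
  }
  if (length(object@terminals) < 2L)
    msg <- c(msg, "composite patterns have >= 2 terminals")
  if (length(msg)) msg else TRUE
})

newTPattern <- function(left, right, ci, occurrences,
                        leftMap = integer(), rightMap = integer(),
                        burst = FALSE) {
  childTerms <- function(x) if (is.character(x)) x else x@terminals
  childLevel <- function(x) if (is.character(x)) 0L else x@level
  occurrences <- matrix(as.integer(occurrences), ncol = 2L,
                        dimnames = list(NULL, c("start", "end")))
  new("TPattern", left = left, right = right, ci = ci,
      occurrences = occurrences,
      terminals = c(childTerms(left), childTerms(right)),
      level = max(childLevel(left), childLevel(right)) + 1L,
      burst = burst,
      leftMap = as.integer(leftMap), rightMap = as.integer(rightMap))
}

#' MonteCarloResult: observed vs surrogate per-length pattern counts
#'
#' Result of the surrogate-data validation: for each pattern length, the
#' number of distinct patterns detected in the original data and the mean
#' and (population) standard deviation of the counts across surrogate
#' randomizations.
#'
#' @slot method \code{"shuffle"} or \code{"rotation"}.
#' @slot nRandomizations Number of surrogates.
#' @slot lengths Integer vector of pattern lengths covered.
#' @slot observed,surrogateMean,surrogateSd Numeric vectors parallel to
#'   \code{lengths}.
#' @export
setClass("MonteCarloResult", representation(
  method = "character", nRandomizations = "integer", lengths = "integer",
  observed = "numeric", surrogateMean = "numeric", surrogateSd = "numeric"
))

setValidity("MonteCarloResult", function(object) {
  msg <- character()
  n <- length(object@lengths)
  if (length(object@observed) != n || length(object@surrogateMean) != n ||
      length(object@surrogateSd) != n)
    msg <- c(msg, "lengths, observed, surrogateMean, surrogateSd must be parallel")
  if (any(object@observed < 0) || any(object@surrogateSd < 0))
    msg <- c(msg, "counts and standard deviations must be non-negative")
  if (!object@method %in% c("shuffle", "rotation"))
    msg <- c(msg, "method must be shuffle or rotation")
  if (length(msg)) msg else TRUE
})
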