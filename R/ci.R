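# sample index (1-based) of each point given sorted sample end times
sampleIndexOf <- function(points, boundaries)
  findInterval(points - 1L, boundaries) + 1L

#' Null probability that a window contains at least one point
#'
#' Under the null hypothesis of independent random placement, a series with
#' \code{nB} points on a period of \code{T} discrete units occupies any
#' given unit with rate \code{nB / T}; the probability that a window of
#' \code{w} units contains at least one point is therefore
#' \code{1 - (1 - nB / T)^w}. Monotone non-decreasing in both \code{nB}
#' and \code{w}.
#'
#' @param nB Number of points of the (right) series.
#' @param T Observation-period length.
#' @param w Window width in time units.
#' @return Probability in \code{[0, 1]}.
#' @examples
#' nullProbWindow(1, 1000, 1)   # 0.001
#' @export
nullProbWindow <- function(nB, T, w) {
  if (any(nB < 0) || any(nB > T) || any(w < 0) || any(T < 1))
    stop("need 0 <= nB <= T and w >= 0")
  1 - (1 - nB / T)^w
}

# Exact upper tail P(X >= h) for independent Bernoulli trials with
# probabilities `probs` (binomial tail when homogeneous).
tailGE <- function(probs, h) tailGECpp(as.numeric(probs), as.integer(h))

# per-trial success probabilities for windows [a + d1, a + d2], truncated at
# each point's sample end; rate = nB / T
trialProbs <- function(a, d1, d2, sampEndA, rate) {
  w <- pmin(a + d2, sampEndA) - (a + d1) + 1
  w <- pmax(0L, pmin(w, d2 - d1 + 1L))
  ifelse(w == 0L, 0, 1 - (1 - rate)^w)
}

#' Exact tail probability for a fixed candidate interval
#'
#' Counts the left points followed by at least one right point within
#' \code{[a + d1, a + d2]} (same sample; windows truncated at sample
#' boundaries) and returns the exact upper-tail probability of at least
#' that many hits when each window independently contains a right point
#' with probability \code{nullProbWindow(length(bPoints), T, w)} for its
#' (possibly truncated) width \code{w}.
#'
#' @param aPoints,bPoints Sorted occurrence times of the left and right
#'   series.
#' @param T Observation-period length.
#' @param d1,d2 Candidate interval, \code{0 <= d1 <= d2}.
#' @param boundaries Sample end times (default: single sample of length T).
#' @return List with \code{pValue} and \code{nHits}. Empty input gives
#'   \code{pValue = 1}, \code{nHits = 0}.
#' @examples
#' ciPValue(c(10, 30, 50), c(13, 33, 70), T = 100, d1 = 3, d2 = 3)
#' @export
ciPValue <- function(aPoints, bPoints, T, d1, d2, boundaries = T) {
  stopifnot(d1 >= 0, d2 >= d1)
  a <- as.integer(aPoints); b <- as.integer(bPoints)
  if (!length(a) || !length(b)) return(list(pValue = 1, nHits = 0L))
  boundaries <- as.integer(boundaries)
  sampA <- sampleIndexOf(a, boundaries)
  sampB <- sampleIndexOf(b, boundaries)
  hit <- vapply(seq_along(a), function(i) {
    inWin <- b >= a[i] + d1 & b <= a[i] + d2 & sampB == sampA[i]
    any(inWin)
  }, logical(1))
  nHits <- sum(hit)
  probs <- trialProbs(a, as.integer(d1), as.integer(d2),
                      boundaries[sampA], length(b) / T)
  list(pValue = tailGE(probs, nHits), nHits = as.integer(nHits))
}

#' Search for a significant critical interval between two point series
#'
#' The relation sought is sequential: "an occurrence of B follows an
#' occurrence of A within \code{[d1, d2]}". Accordingly, both the candidate
#' intervals and the hit events are defined through the distance from each
#' A point to its \emph{next following} B point (same sample, capped at
#' \code{dMax}): candidate endpoints are the observed next-following
#' distances, and a left point is a hit when its next-following distance
#' lies in the interval. Under the null of independent placement at
#' per-unit rate \code{q = nB / T}, the per-trial hit probability for a
#' (possibly sample-boundary-truncated) window of width \code{w} is
#' \code{(1 - q)^d1 * (1 - (1 - q)^w)}. The candidate with exact tail
#' probability at most \code{alpha} and at least \code{nMin} hits that
#' minimizes the tail probability is returned, ties broken by smaller
#' width then smaller \code{d1}; \code{NULL} when no candidate qualifies
#' (a normal outcome).
#'
#' Because the candidate set is data-driven, testing every candidate
#' against \code{alpha} directly would make a spurious interval
#' near-certain whenever many distances are observed. The scan therefore
#' applies a Bonferroni-style selection control: a candidate qualifies
#' when its exact tail probability is at most \code{alpha / K}, where
#' \code{K} is the number of distinct observed candidate distances
#' (nested candidates sharing a seed distance are near-duplicates, so
#' \code{K} is the effective family size). In mode \code{"fixed11"} the
#' single interval \code{[1, 1]} is tested at \code{alpha} itself.
#'
#' In mode \code{"fixed11"} only \code{[1, 1]} is tested. In mode
#' \code{"burst"} the series is related to itself: candidates are
#' \code{[0, d2]} with \code{d2} drawn from the successive-point gaps, a
#' point is a hit when the next point of the same sample follows within
#' \code{d2}, and the null rate excludes the focal point
#' (\code{(n - 1) / T}); no minimum hit count is imposed beyond 1, since a
#' burst run itself requires at least two points.
#'
#' @param aPoints,bPoints Sorted occurrence times. For burst mode pass the
#'   same series twice.
#' @param T Observation-period length.
#' @param params A [DetectionParams-class] object.
#' @param boundaries Sample end times.
#' @return A [CriticalInterval-class] or \code{NULL}.
#' @examples
#' detectCriticalInterval(c(10, 30, 50), c(13, 33, 53), T = 1000,
#'                        detectionParams())
#' @export
detectCriticalInterval <- function(aPoints, bPoints, T,
                                   params = detectionParams(),
                                   boundaries = T) {
  stopifnot(is(params, "DetectionParams"))
  a <- as.integer(aPoints); b <- as.integer(bPoints)
  if (!length(a) || !length(b)) return(NULL)
  boundaries <- as.integer(boundaries)
  T <- as.integer(T)
  dMax <- if (is.na(params@dMax)) T - 1L else min(params@dMax, T - 1L)
  sampA <- sampleIndexOf(a, boundaries)
  sampB <- sampleIndexOf(b, boundaries)

  if (params@mode == "burst") {
    n <- length(a)
    if (n < 2L) return(NULL)
    gaps <- diff(a)
    sameSamp <- diff(sampA) == 0L
    cand <- sort(unique(gaps[sameSamp & gaps <= dMax]))
    if (!length(cand)) return(NULL)
    rate <- (n - 1) / T
    alphaEff <- params@alpha / length(cand)   # selection control, see docs
    best <- NULL
    for (d2 in cand) {
      nHits <- sum(gaps <= d2 & sameSamp)
      probs <- trialProbs(a, 0L, d2, boundaries[sampA], rate)
      p <- tailGE(probs, nHits)
      if (p <= alphaEff && nHits >= 1L &&
          (is.null(best) || p < best@pValue))
        best <- CriticalInterval(0L, d2, p, nHits)
    }
    return(best)
  }

  mode <- if (params@mode == "fixed11") "fixed11" else "general"
  res <- ciScanCpp(a, b, sampA, sampB, boundaries[sampA],
                   length(b) / T, dMax, params@alpha, params@nMin, mode)
  if (is.null(res)) return(NULL)
  CriticalInterval(res$d1, res$d2, res$pValue, res$nHits)
}
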