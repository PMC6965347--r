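# ---- occurrence pairing ----------------------------------------------------

#' Pair left and right occurrences through a critical interval
#'
#' Greedy earliest matching: left occurrences are scanned in time order and
#' each is joined to the earliest unused right occurrence whose start
#' \code{s} satisfies \code{d1 <= s - e <= d2} (\code{e} the left end)
#' within the same sample. Each occurrence is used at most once, so the
#' resulting list is non-overlapping in the pairing sense.
#'
#' @param leftOcc,rightOcc Integer matrices (start, end), sorted by start.
#' @param d1,d2 The critical interval.
#' @param boundaries Sample end times (default: one sample covering both).
#' @return List with \code{occ} (matrix of (left start, right end) rows),
#'   \code{leftMap} and \code{rightMap} (matched row indices).
#' @examples
#' l <- cbind(c(5L, 20L), c(5L, 20L)); r <- cbind(c(9L, 26L), c(9L, 26L))
#' pairOccurrences(l, r, 3, 6)$occ
#' @export
pairOccurrences <- function(leftOcc, rightOcc, d1, d2,
                            boundaries = max(leftOcc, rightOcc)) {
  boundaries <- as.integer(boundaries)
  sampL <- sampleIndexOf(leftOcc[, 2L], boundaries)
  sampR <- sampleIndexOf(rightOcc[, 1L], boundaries)
  pm <- pairOccurrencesCpp(leftOcc[, 1L], leftOcc[, 2L],
                           rightOcc[, 1L], rightOcc[, 2L],
                           sampL, sampR, as.integer(d1), as.integer(d2))
  lm <- pm$leftMap; rm <- pm$rightMap
  occ <- cbind(start = leftOcc[lm, 1L], end = rightOcc[rm, 2L])
  if (!length(lm)) occ <- matrix(integer(), ncol = 2L,
                                 dimnames = list(NULL, c("start", "end")))
  list(occ = occ, leftMap = lm, rightMap = rm)
}

# labels of terminals of `node`'s occurrence `row` realized exactly at time
# t; used to detect degenerate zero-gap pairings that would reuse the same
# underlying (series, time) point in both parts of a pattern
labelsAtTime <- function(node, row, t, series) {
  if (is.character(node))
    return(if (series[[node]][row] == t) node else character(0))
  occ <- node@occurrences
  if (t < occ[row, 1L] || t > occ[row, 2L]) return(character(0))
  if (node@burst) {
    pts <- series[[node@terminals[1L]]]
    hasPt <- any(pts >= occ[row, 1L] & pts <= occ[row, 2L] & pts == t)
    return(if (hasPt) node@terminals[1L] else character(0))
  }
  c(labelsAtTime(node@left, node@leftMap[row], t, series),
    labelsAtTime(node@right, node@rightMap[row], t, series))
}

# greedy pairing with the zero-gap point-reuse rule: a right occurrence
# whose start coincides with the left end and would reuse the same
# (series, time) point is skipped in favor of the next eligible one
pairNoReuse <- function(P, Q, d1, d2, bounds, series) {
  lOcc <- P$occ; rOcc <- Q$occ
  sampL <- sampleIndexOf(lOcc[, 2L], bounds)
  sampR <- sampleIndexOf(rOcc[, 1L], bounds)
  used <- logical(nrow(rOcc))
  lm <- rm <- integer(0)
  for (i in seq_len(nrow(lOcc))) {
    e <- lOcc[i, 2L]
    for (j in seq_len(nrow(rOcc))) {
      if (used[j]) next
      gap <- rOcc[j, 1L] - e
      if (gap > d2) break
      if (gap < d1 || sampR[j] != sampL[i]) next
      if (gap == 0L && length(intersect(
            labelsAtTime(P$src, i, e, series),
            labelsAtTime(Q$src, j, e, series)))) next
      used[j] <- TRUE
      lm <- c(lm, i); rm <- c(rm, j)
      break
    }
  }
  occ <- cbind(start = lOcc[lm, 1L], end = rOcc[rm, 2L])
  if (!length(lm)) occ <- matrix(integer(), ncol = 2L,
                                 dimnames = list(NULL, c("start", "end")))
  list(occ = occ, leftMap = lm, rightMap = rm)
}

# ---- working-series bookkeeping -------------------------------------------

terminalOcc <- function(points) cbind(start = points, end = points)

patternKey <- function(p)
  paste(paste(p@terminals, collapse = "\x1f"),
        paste(p@occurrences, collapse = ","), sep = "|")

# ---- completeness competition ---------------------------------------------

isSubsequence <- function(x, y) {
  i <- 1L
  for (el in y) {
    if (i > length(x)) return(TRUE)
    if (identical(x[i], el)) i <- i + 1L
  }
  i > length(x)
}

# terminal (label, time) realization of every occurrence: n x m matrix of
# times, columns in terminal order
patternTerminalTimes <- function(p, series) {
  f <- function(node, rows) {
    if (is.character(node))
      return(matrix(series[[node]][rows], ncol = 1L))
    if (node@burst)
      return(cbind(node@occurrences[rows, 1L], node@occurrences[rows, 2L]))
    cbind(f(node@left, node@leftMap[rows]),
          f(node@right, node@rightMap[rows]))
  }
  f(p, seq_len(nrow(p@occurrences)))
}

# is the labelled time sequence (labX, tX) a subsequence of (labY, tY)?
timedSubseq <- function(labX, tX, labY, tY) {
  i <- 1L
  for (j in seq_along(labY)) {
    if (i > length(labX)) return(TRUE)
    if (labX[i] == labY[j] && tX[i] == tY[j]) i <- i + 1L
  }
  i > length(labX)
}

# generic bipartite matching (augmenting paths): can every row i of X be
# assigned a distinct row j of Y with compatible(i, j)?
matchRows <- function(np, nq, adj) {
  matchQ <- integer(nq)
  tryAssign <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (matchQ[j] == 0L || Recall(matchQ[j], seen)) {
        matchQ[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(np))
    if (!tryAssign(i, logical(nq))) return(FALSE)
  TRUE
}

# can every row of pOcc be placed inside a distinct containing row of qOcc?
occContained <- function(pOcc, qOcc) {
  np <- nrow(pOcc); nq <- nrow(qOcc)
  if (np > nq) return(FALSE)
  adj <- lapply(seq_len(np), function(i)
    which(qOcc[, 1L] <= pOcc[i, 1L] & qOcc[, 2L] >= pOcc[i, 2L]))
  matchRows(np, nq, adj)
}

# stronger notion when raw series are available: every occurrence of P
# must be realized inside a distinct occurrence of Q using the very same
# terminal points (labelled times embed as a subsequence)
occEmbedded <- function(p, q, series) {
  ttP <- patternTerminalTimes(p, series)
  ttQ <- patternTerminalTimes(q, series)
  labP <- patternTerminals(p); labQ <- patternTerminals(q)
  np <- nrow(ttP); nq <- nrow(ttQ)
  if (np > nq) return(FALSE)
  adj <- lapply(seq_len(np), function(i)
    Filter(function(j) timedSubseq(labP, ttP[i, ], labQ, ttQ[j, ]),
           seq_len(nq)))
  matchRows(np, nq, adj)
}

#' Remove redundant detections of the same underlying pattern
#'
#' Two rules. (1) A pattern P is dropped when some other pattern Q carries
#' the same information more completely: P's terminal sequence is an
#' ordered subsequence of Q's, both have equally many occurrences, and each
#' occurrence of P is realized inside a distinct occurrence of Q. When the
#' raw series are supplied, "realized inside" is checked at the level of
#' terminal points — Q must use the very same (series, time) points, so an
#' unrelated larger pattern that merely spans the same stretch of time
#' does not absorb P; without series only span containment can be checked.
#' (2) Among patterns with identical terminal sequence and identical
#' occurrence list but different tree shapes, only the one with the
#' smallest maximal node p-value survives (ties: first constructed).
#'
#' @param candidates List of [TPattern-class] objects, in construction
#'   order.
#' @param series Optional named list of raw series points (as in a
#'   [TData-class]), enabling the point-level redundancy check.
#' @return Filtered list, construction order preserved.
#' @export
completenessCompetition <- function(candidates, series = NULL) {
  if (length(candidates) <= 1L) return(candidates)
  keys <- vapply(candidates, patternKey, "")
  keep <- !logical(length(candidates))
  # rule 2: dedup identical (terminals, occurrences) by smaller max node p
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    best <- idx[which.min(vapply(candidates[idx], maxNodeP, 0))]
    keep[setdiff(idx, best)] <- FALSE
  }
  live <- which(keep)
  # rule 1: containment with equal occurrence counts
  terms <- lapply(candidates, patternTerminals)
  ns <- vapply(candidates, nOccurrences, 0L)
  drop <- logical(length(candidates))
  for (i in live) for (j in live) {
    if (i == j || ns[i] != ns[j]) next
    if (length(terms[[i]]) >= length(terms[[j]])) next
    if (!isSubsequence(terms[[i]], terms[[j]])) next
    redundant <- if (is.null(series))
      occContained(candidates[[i]]@occurrences, candidates[[j]]@occurrences)
    else occEmbedded(candidates[[i]], candidates[[j]], series)
    if (redundant) { drop[i] <- TRUE; break }
  }
  candidates[keep & !drop]
}

# ---- burst detection -------------------------------------------------------

#' Detect T-bursts in a single point series
#'
#' A T-burst is a significant dense run within one series, defined by a
#' fast critical interval \code{[0, d2]}: the interval is searched over the
#' observed successive-point gaps (see [detectCriticalInterval()], burst
#' mode), and if one is significant the burst instances are the maximal
#' runs of two or more consecutive points with gaps at most \code{d2}.
#'
#' @param label Event-type label of the series within \code{data}.
#' @param data A [TData-class] object.
#' @param params [DetectionParams-class]; \code{alpha} and \code{dMax} are
#'   used.
#' @return List of zero or one [TPattern-class] burst objects (one pattern
#'   whose occurrences are the runs).
#' @export
detectTBursts <- function(label, data, params = detectionParams()) {
  stopifnot(is(data, "TData"))
  pts <- seriesPoints(data, label)
  if (length(pts) < 2L) return(list())
  bparams <- params
  bparams@mode <- "burst"
  ci <- detectCriticalInterval(pts, pts, periodLength(data), bparams,
                               sampleBoundaries(data))
  if (is.null(ci)) return(list())
  samp <- sampleIndexOf(pts, sampleBoundaries(data))
  newRun <- c(TRUE, diff(pts) > ci@d2 | diff(samp) != 0L)
  runId <- cumsum(newRun)
  runs <- which(tabulate(runId) >= 2L)
  if (!length(runs)) return(list())
  occ <- t(vapply(runs, function(r) {
    idx <- which(runId == r)
    c(pts[idx[1L]], pts[idx[length(idx)]])
  }, integer(2)))
  first <- vapply(runs, function(r) which(runId == r)[1L], integer(1))
  last <- vapply(runs, function(r) { i <- which(runId == r); i[length(i)] },
                 integer(1))
  list(newTPattern(label, label, ci, occ, leftMap = first, rightMap = last,
                   burst = TRUE))
}

# ---- bottom-up detection ---------------------------------------------------

#' Detect T-patterns in T-data
#'
#' Bottom-up binary-tree construction. The working set is initialized with
#' all event series; on each pass, every ordered pair of distinct working
#' series (lengths summing to at most \code{maxLength}) is tested for a
#' critical interval relating the left part's end points to the right
#' part's start points. Each significant interval yields a candidate
#' pattern by greedy occurrence pairing; candidates with at least
#' \code{nMin} occurrences enter the completeness competition together with
#' all previously surviving patterns, and survivors join the working set
#' for the next pass. The search stops at a fixpoint or after
#' \code{maxLevels} passes.
#'
#' In mode \code{"burst"}, each original series is additionally searched
#' for T-bursts before the first pass and significant bursts join the
#' working set (so bursts can nest inside larger patterns). In mode
#' \code{"fixed11"} only the critical interval \code{[1, 1]} is tested,
#' which on sequence-derived data (see [sequenceToTData()]) recovers
#' recurrent contiguous strings.
#'
#' @param data A [TData-class] object.
#' @param params A [DetectionParams-class] object.
#' @return List of surviving composite [TPattern-class] objects, sorted by
#'   decreasing length then increasing root p-value. Deterministic for
#'   identical input.
#' @examples
#' td <- TData(list(a = c(10L, 110L, 210L), b = c(15L, 115L, 215L)),
#'             period = 1000)
#' detectTPatterns(td, detectionParams())
#' @export
detectTPatterns <- function(data, params = detectionParams()) {
  stopifnot(is(data, "TData"), is(params, "DetectionParams"))
  if (!length(data@series)) return(list())
  T <- periodLength(data)
  bounds <- sampleBoundaries(data)
  scanMode <- switch(params@mode, fixed11 = "fixed11", "general")
  dMax <- if (is.na(params@dMax)) T - 1L else min(params@dMax, T - 1L)

  # per-entry precomputation for the C-level interval scan
  wsEntry <- function(id, src, m, occ) {
    aEnd <- sort.int(occ[, 2L])
    sampA <- sampleIndexOf(aEnd, bounds)
    list(id = id, src = src, m = m, occ = occ,
         aEnd = aEnd, sampA = sampA, sampEndA = bounds[sampA],
         bStart = occ[, 1L], sampB = sampleIndexOf(occ[, 1L], bounds))
  }
  patEntry <- function(p)
    wsEntry(paste0("p:", patternKey(p)), p, patternLength(p), p@occurrences)

  ws <- lapply(eventLabels(data), function(lab)
    wsEntry(paste0("t:", lab), lab, 1L,
            terminalOcc(seriesPoints(data, lab))))
  patterns <- list()
  if (params@mode == "burst") {
    for (lab in eventLabels(data))
      patterns <- c(patterns, detectTBursts(lab, data, params))
    for (p in patterns) ws[[length(ws) + 1L]] <- patEntry(p)
  }

  tested <- new.env(hash = TRUE, parent = emptyenv())
  for (pass in seq_len(params@maxLevels)) {
    newPats <- list()
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (p in patterns) seen[[patternKey(p)]] <- TRUE
    for (i in seq_along(ws)) for (j in seq_along(ws)) {
      if (i == j) next
      P <- ws[[i]]; Q <- ws[[j]]
      if (P$m + Q$m > params@maxLength) next
      if (nrow(P$occ) < params@nMin) next   # hits cannot reach nMin
      pairId <- paste(P$id, Q$id, sep = " \x1f ")
      if (!is.null(tested[[pairId]])) next
      tested[[pairId]] <- TRUE
      res <- ciScanCpp(P$aEnd, Q$bStart, P$sampA, Q$sampB, P$sampEndA,
                       nrow(Q$occ) / T, dMax, params@alpha, params@nMin,
                       scanMode)
      if (is.null(res)) next
      ci <- CriticalInterval(res$d1, res$d2, res$pValue, res$nHits)
      pr <- if (ci@d1 == 0L)
        pairNoReuse(P, Q, ci@d1, ci@d2, bounds, data@series)
      else pairOccurrences(P$occ, Q$occ, ci@d1, ci@d2, bounds)
      if (nrow(pr$occ) < params@nMin) next
      cand <- newTPattern(P$src, Q$src, ci, pr$occ,
                          leftMap = pr$leftMap, rightMap = pr$rightMap)
      ck <- patternKey(cand)
      if (!is.null(seen[[ck]])) next
      seen[[ck]] <- TRUE
      newPats[[length(newPats) + 1L]] <- cand
    }
    if (!length(newPats)) break
    surviving <- completenessCompetition(c(patterns, newPats), data@series)
    if (identical(vapply(surviving, patternKey, ""),
                  vapply(patterns, patternKey, "")))
      break
    patterns <- surviving
    ws <- ws[vapply(ws, function(e) e$m == 1L, logical(1))]
    for (p in patterns) ws[[length(ws) + 1L]] <- patEntry(p)
  }
  composite <- patterns
  rootP <- vapply(composite, function(p) p@ci@pValue, 0)
  m <- vapply(composite, patternLength, 0L)
  composite[order(-m, rootP)]
}

# ---- independent re-verification ------------------------------------------

#' Re-verify a detected pattern against raw data
#'
#' Rechecks every structural invariant of a [TPattern-class] from the raw
#' [TData-class], trusting nothing from the builder: occurrences sorted and
#' each within one sample; at every internal node and for every occurrence
#' the realized gap between the left part's end and the right part's start
#' lies within that node's critical interval; every terminal time is an
#' actual point of the corresponding series; child occurrences are used at
#' most once; all node p-values are at most \code{alpha}; and (for
#' non-burst patterns) the occurrence count is at least \code{nMin}. Burst
#' occurrences are checked to be runs of two or more series points with
#' internal gaps at most \code{d2}, maximal on both sides.
#'
#' @param pattern A [TPattern-class] object.
#' @param data The [TData-class] it was detected in.
#' @param params The [DetectionParams-class] used for detection.
#' @return \code{TRUE} if all checks pass, otherwise a character vector of
#'   problems.
#' @export
verifyTPattern <- function(pattern, data, params = detectionParams()) {
  bounds <- sampleBoundaries(data)
  probs <- character()
  note <- function(...) probs <<- c(probs, sprintf(...))
  occ <- pattern@occurrences
  if (nrow(occ) && is.unsorted(occ[, 1L])) note("occurrences not sorted")
  samp1 <- sampleIndexOf(occ[, 1L], bounds)
  samp2 <- sampleIndexOf(occ[, 2L], bounds)
  if (any(samp1 != samp2)) note("occurrence crosses a sample boundary")
  if (!pattern@burst && nrow(occ) < params@nMin)
    note("fewer than nMin occurrences")
  ciTab <- criticalIntervals(pattern)
  if (any(ciTab$pValue > params@alpha))
    note("node p-value exceeds alpha")

  # burst node: each used occurrence must be a run of >= 2 series points
  # with internal gaps <= d2, maximal on both sides within its sample
  checkBurst <- function(node, rows) {
    pts <- data@series[[node@terminals[1L]]]
    if (is.null(pts)) { note("burst series missing from data"); return(NULL) }
    d2 <- node@ci@d2
    samp <- sampleIndexOf(pts, bounds)
    nocc <- node@occurrences
    for (k in rows) {
      sk <- sampleIndexOf(nocc[k, 1L], bounds)
      idx <- which(pts >= nocc[k, 1L] & pts <= nocc[k, 2L] & samp == sk)
      if (length(idx) < 2L || pts[idx[1L]] != nocc[k, 1L] ||
          pts[idx[length(idx)]] != nocc[k, 2L]) {
        note("burst occurrence %d endpoints not series points", k); next
      }
      if (any(diff(pts[idx]) > d2))
        note("burst occurrence %d has an internal gap > d2", k)
      lo <- idx[1L]; hi <- idx[length(idx)]
      if (lo > 1L && samp[lo - 1L] == samp[lo] && pts[lo] - pts[lo - 1L] <= d2)
        note("burst occurrence %d not left-maximal", k)
      if (hi < length(pts) && samp[hi + 1L] == samp[hi] &&
          pts[hi + 1L] - pts[hi] <= d2)
        note("burst occurrence %d not right-maximal", k)
    }
    cbind(nocc[rows, 1L], nocc[rows, 2L])
  }

  # recursively check spans; `rows` are occurrence rows of `node` in use
  checkNode <- function(node, rows) {
    if (is.character(node)) {
      pts <- data@series[[node]]
      if (is.null(pts)) { note("terminal '%s' missing from data", node)
                          return(NULL) }
      if (any(rows < 1L | rows > length(pts))) {
        note("terminal '%s': occurrence index out of range", node)
        return(NULL)
      }
      return(cbind(pts[rows], pts[rows]))
    }
    if (anyDuplicated(rows)) note("occurrence row reused at a node")
    if (node@burst) return(checkBurst(node, rows))
    nocc <- node@occurrences
    lspan <- checkNode(node@left, node@leftMap[rows])
    rspan <- checkNode(node@right, node@rightMap[rows])
    if (is.null(lspan) || is.null(rspan)) return(NULL)
    gap <- rspan[, 1L] - lspan[, 2L]
    if (any(gap < node@ci@d1 | gap > node@ci@d2))
      note("realized gap outside [%d, %d]", node@ci@d1, node@ci@d2)
    for (k in which(gap == 0L)) {
      shared <- intersect(
        labelsAtTime(node@left, node@leftMap[rows[k]], lspan[k, 2L],
                     data@series),
        labelsAtTime(node@right, node@rightMap[rows[k]], rspan[k, 1L],
                     data@series))
      if (length(shared))
        note("zero-gap occurrence reuses a point of '%s'", shared[1L])
    }
    span <- cbind(lspan[, 1L], rspan[, 2L])
    bad <- which(span[, 1L] != nocc[rows, 1L] | span[, 2L] != nocc[rows, 2L])
    if (length(bad)) note("stored occurrence span disagrees with children")
    span
  }
  checkNode(pattern, seq_len(nrow(occ)))
  if (length(probs)) probs else TRUE
}
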