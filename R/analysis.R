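#' Per-pattern summary statistics
#'
#' Computes the quantities typically analyzed after detection: length m,
#' tree level, occurrence count n, number of distinct actors, number of
#' actor switches (adjacent terminal pairs with different actors), and the
#' realized span (end - start) summaries. Actors come from the
#' "actor,phase,behavior" label convention (see [parseEventLabels()]);
#' terminals not following it are excluded from actor statistics.
#'
#' @param pattern A [TPattern-class] object.
#' @return One-row data.frame with columns \code{terminals}, \code{m},
#'   \code{level}, \code{n}, \code{actors}, \code{switches},
#'   \code{minSpan}, \code{maxSpan}, \code{meanSpan}.
#' @export
patternStats <- function(pattern) {
  stopifnot(is(pattern, "TPattern"))
  terms <- patternTerminals(pattern)
  actors <- parseEventLabels(terms)$actor
  known <- actors[nzchar(actors)]
  adjacent <- actors[-length(actors)]
  nextOne <- actors[-1L]
  ok <- nzchar(adjacent) & nzchar(nextOne)
  spans <- pattern@occurrences[, 2L] - pattern@occurrences[, 1L]
  data.frame(
    terminals = paste(terms, collapse = " "),
    m = patternLength(pattern),
    level = patternLevel(pattern),
    n = nOccurrences(pattern),
    actors = length(unique(known)),
    switches = sum(ok & adjacent != nextOne),
    minSpan = if (length(spans)) min(spans) else NA_integer_,
    maxSpan = if (length(spans)) max(spans) else NA_integer_,
    meanSpan = if (length(spans)) mean(spans) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Select patterns by content, order and interactivity
#'
#' Keeps patterns whose terminals contain all \code{required} event-types:
#' as an ordered subsequence when \code{ordered = TRUE}, as a multiset
#' otherwise. \code{multiActorOnly} additionally requires at least two
#' distinct actors among the terminals (interaction / synchronization
#' candidates). Filters are idempotent and commute.
#'
#' @param patterns List of [TPattern-class] objects.
#' @param required Character vector of event-type labels (empty: no
#'   content filter).
#' @param ordered Require \code{required} in the given order.
#' @param multiActorOnly Keep only patterns with >= 2 distinct actors.
#' @param known Labels considered valid; defaults to those occurring in
#'   \code{patterns}. Unknown \code{required} labels are an error.
#' @return Filtered list.
#' @export
selectPatterns <- function(patterns, required = character(),
                           ordered = FALSE, multiActorOnly = FALSE,
                           known = NULL) {
  allTerms <- unique(unlist(lapply(patterns, patternTerminals)))
  if (is.null(known)) known <- allTerms
  bad <- setdiff(required, known)
  if (length(bad))
    stop("unknown event-type(s) ", paste(bad, collapse = ", "),
         "; known: ", paste(sort(known), collapse = ", "))
  keep <- vapply(patterns, function(p) {
    terms <- patternTerminals(p)
    contentOk <- if (!length(required)) TRUE
      else if (ordered) isSubsequence(required, terms)
      else {
        req <- table(required)
        all(req <= table(factor(terms, levels = names(req))))
      }
    actorOk <- if (!multiActorOnly) TRUE else {
      a <- parseEventLabels(terms)$actor
      length(unique(a[nzchar(a)])) >= 2L
    }
    contentOk && actorOk
  }, logical(1))
  patterns[keep]
}

#' Inventory of event-types across detected patterns
#'
#' Lists every event-type occurring as a terminal in any pattern together
#' with the minimum tree depth at which it appears (root = 0, so direct
#' children of the root are at level 1).
#'
#' @param patterns List of [TPattern-class] objects.
#' @return data.frame with columns \code{label} and \code{firstLevel},
#'   sorted by label; empty for an empty pattern list.
#' @export
eventTypeInventory <- function(patterns) {
  depths <- new.env(parent = emptyenv())
  walk <- function(node, depth) {
    if (is.character(node)) {
      cur <- depths[[node]]
      if (is.null(cur) || depth < cur) depths[[node]] <- depth
      return(invisible())
    }
    walk(node@left, depth + 1L)
    walk(node@right, depth + 1L)
  }
  for (p in patterns) walk(p, 0L)
  labs <- sort(ls(depths))
  data.frame(label = labs,
             firstLevel = vapply(labs, function(l) depths[[l]], integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

ciString <- function(pattern) {
  tab <- criticalIntervals(pattern)
  paste(sprintf("[%d,%d]p=%.3g", tab$d1, tab$d2, tab$pValue), collapse = ";")
}

#' Export a pattern table for external statistical analysis
#'
#' One row per pattern: id, terminal string, m, level, n, actors, switches,
#' and the per-node critical intervals with p-values. Tab-separated, stable
#' column order, deterministic byte-for-byte for identical input.
#'
#' @param patterns List of [TPattern-class] objects.
#' @param target File path or connection.
#' @return Invisibly, the exported data.frame.
#' @export
exportPatternTable <- function(patterns, target) {
  rows <- lapply(seq_along(patterns), function(i) {
    st <- patternStats(patterns[[i]])
    cbind(id = i, st, burst = isBurst(patterns[[i]]),
          rootP = patterns[[i]]@ci@pValue,
          criticalIntervals = ciString(patterns[[i]]))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), terminals = character(), m = integer(),
               level = integer(), n = integer(), actors = integer(),
               switches = integer(), minSpan = integer(),
               maxSpan = integer(), meanSpan = numeric(),
               burst = logical(), rootP = numeric(),
               criticalIntervals = character())
  utils::write.table(tab, target, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Export a static pattern diagram
#'
#' Writes (a) a DOT graph description of the pattern's binary tree with
#' critical-interval labels and (b) a JSON point-map listing, per involved
#' series (in terminal order), its occurrence points and the terminal
#' times of each pattern occurrence, i.e. the level-by-level connections
#' that form the pattern.
#'
#' @param pattern A [TPattern-class] object.
#' @param data The [TData-class] the pattern was detected in.
#' @param dotTarget,jsonTarget Output file paths (either may be
#'   \code{NULL} to skip).
#' @return Invisibly, the point-map list.
#' @export
exportPatternDiagram <- function(pattern, data, dotTarget = NULL,
                                 jsonTarget = NULL) {
  stopifnot(is(pattern, "TPattern"), is(data, "TData"))
  missing <- setdiff(patternTerminals(pattern), eventLabels(data))
  if (length(missing))
    stop("pattern event-types absent from data: ",
         paste(missing, collapse = ", "))

  if (!is.null(dotTarget)) {
    lines <- c("digraph tpattern {", "  node [shape=box];")
    counter <- 0L
    emit <- function(node) {
      counter <<- counter + 1L
      id <- sprintf("n%d", counter)
      if (is.character(node)) {
        lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, node))
      } else {
        lines <<- c(lines, sprintf(
          "  %s [label=\"[%d,%d]\\np=%.3g\" shape=ellipse];",
          id, node@ci@d1, node@ci@d2, node@ci@pValue))
        lid <- emit(node@left); rid <- emit(node@right)
        lines <<- c(lines, sprintf("  %s -> %s;", id, lid),
                    sprintf("  %s -> %s;", id, rid))
      }
      id
    }
    emit(pattern)
    writeLines(c(lines, "}"), dotTarget)
  }

  tt <- patternTerminalTimes(pattern, data@series)
  pointMap <- list(
    terminals = patternTerminals(pattern),
    series = lapply(setNames(nm = unique(patternTerminals(pattern))),
                    function(l) data@series[[l]]),
    connections = lapply(seq_len(nrow(tt)), function(k)
      as.integer(tt[k, ]))
  )
  if (!is.null(jsonTarget))
    jsonlite::write_json(pointMap, jsonTarget, auto_unbox = TRUE)
  invisible(pointMap)
}
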