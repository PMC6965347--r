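# ---- synthetic T-data with known ground truth ------------------------------

#' Generate independent uniform noise T-data
#'
#' Each series gets \code{pointsPerSeries} distinct times drawn uniformly
#' without replacement from \code{[1, T]}; series are labeled
#' \code{noise_1 .. noise_n}. Deterministic per seed. This is the null
#' background of the study conditions: independent random placement with
#' no temporal structure.
#'
#' @param nSeries Number of series.
#' @param pointsPerSeries Points per series (at most \code{T}).
#' @param T Observation-period length.
#' @param seed Integer seed.
#' @param labels Optional labels (default \code{noise_1..}).
#' @return A [TData-class] object.
#' @examples
#' generateNoiseTData(5, 20, 10000, seed = 1)
#' @export
generateNoiseTData <- function(nSeries, pointsPerSeries, T, seed,
                               labels = paste0("noise_", seq_len(nSeries))) {
  if (pointsPerSeries > T) stop("pointsPerSeries must not exceed T")
  if (nSeries == 0L) return(TData(list(), period = T))
  stopifnot(length(labels) == nSeries)
  withLocalSeed(seed, {
    series <- lapply(seq_len(nSeries), function(i)
      sort(sample.int(T, pointsPerSeries)))
    names(series) <- labels
    TData(series, period = T)
  })
}

#' Template for a planted hierarchical pattern
#'
#' @param labels Terminal event-type labels, in order.
#' @param gaps For the m terminals, m-1 gap specifications: either a
#'   single integer (fixed gap) or a length-2 vector \code{c(g1, g2)}
#'   (gap drawn uniformly in \code{[g1, g2]} per instance). Gaps are the
#'   distances between consecutive terminal times.
#' @param k Number of instances to plant.
#' @return A \code{PatternTemplate} list used by [plantPattern()].
#' @export
patternTemplate <- function(labels, gaps, k) {
  if (!is.list(gaps)) gaps <- as.list(gaps)
  stopifnot(length(labels) >= 2L, length(gaps) == length(labels) - 1L,
            k >= 1L)
  for (g in gaps)
    stopifnot(length(g) %in% 1:2, all(g >= 0), !is.unsorted(g))
  structure(list(labels = labels, gaps = gaps, k = as.integer(k)),
            class = "PatternTemplate")
}

#' Plant pattern instances into T-data
#'
#' Places \code{k} non-overlapping instances of the template at random
#' start times; fixed gaps are realized exactly, jittered gaps are drawn
#' uniformly within their interval. Existing points of the involved series
#' are left untouched; a planted time colliding with an existing point of
#' the same series triggers a re-draw of that instance. Returns the
#' ground-truth occurrence spans for recovery scoring.
#'
#' @param data A [TData-class] object to plant into.
#' @param template A [patternTemplate()].
#' @param seed Integer seed.
#' @param maxTries Re-draw budget before giving up.
#' @return List with \code{data} (the augmented [TData-class]) and
#'   \code{truth} (matrix of planted terminal times, one row per instance,
#'   one column per terminal, sorted by start).
#' @export
plantPattern <- function(data, template, seed, maxTries = 1000L) {
  stopifnot(is(data, "TData"), inherits(template, "PatternTemplate"))
  T <- periodLength(data)
  maxSpan <- sum(vapply(template$gaps, max, 0))
  if (maxSpan + 1 > T) stop("template does not fit within the period")
  series <- data@series
  for (lab in setdiff(template$labels, names(series)))
    series[[lab]] <- integer(0)
  withLocalSeed(seed, {
    placed <- matrix(0L, nrow = 0L, ncol = length(template$labels))
    tries <- 0L
    while (nrow(placed) < template$k) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("cannot place ", template$k, " non-overlapping instances")
      start <- sample.int(T - maxSpan, 1L)
      gaps <- vapply(template$gaps, function(g)
        if (length(g) == 1L) as.integer(g)
        else as.integer(g[1L] + sample.int(g[2L] - g[1L] + 1L, 1L) - 1L),
        integer(1))
      times <- cumsum(c(start, gaps))
      # instance must not overlap previously planted spans
      if (nrow(placed) &&
          any(times[1L] <= placed[, ncol(placed)] &
              times[length(times)] >= placed[, 1L])) next
      # and must not duplicate existing points of the same series
      dup <- FALSE
      for (idx in seq_along(template$labels))
        if (times[idx] %in% series[[template$labels[idx]]]) dup <- TRUE
      if (dup || anyDuplicated(cbind(template$labels, times))) next
      for (idx in seq_along(template$labels)) {
        lab <- template$labels[idx]
        series[[lab]] <- sort(c(series[[lab]], times[idx]))
      }
      placed <- rbind(placed, times)
    }
    placed <- placed[order(placed[, 1L]), , drop = FALSE]
    dimnames(placed) <- list(NULL, template$labels)
    list(data = TData(series, period = T,
                      sampleBoundaries = sampleBoundaries(data)),
         truth = placed)
  })
}

#' Generate random text with a planted word
#'
#' Produces a string of uniform random letters with \code{word} inserted
#' (overwritten in place) at \code{k} non-overlapping random positions.
#' With \code{backgroundExcludesWordLetters} the background alphabet
#' excludes the word's letters, isolating the recurrence signal of the
#' planted word from chance letter coincidences.
#'
#' @param length Total string length.
#' @param alphabet Background alphabet (a string), default a-z.
#' @param word The word to plant.
#' @param k Number of copies (0 gives a pure negative control).
#' @param backgroundExcludesWordLetters Logical, see above.
#' @param seed Integer seed.
#' @return List with \code{text} (the string) and \code{positions}
#'   (1-based insertion starts, sorted).
#' @examples
#' generateTextWithPlants(200, word = "pattern", k = 2, seed = 1)$positions
#' @export
generateTextWithPlants <- function(length,
                                   alphabet = "abcdefghijklmnopqrstuvwxyz",
                                   word, k,
                                   backgroundExcludesWordLetters = TRUE,
                                   seed = 1) {
  stopifnot(nchar(word) >= 1L, k >= 0L)
  if (k * nchar(word) > length) stop("word copies do not fit")
  letters_ <- strsplit(tolower(alphabet), "")[[1L]]
  wordChars <- strsplit(tolower(word), "")[[1L]]
  bg <- if (backgroundExcludesWordLetters)
    setdiff(letters_, wordChars) else letters_
  if (!length(bg)) stop("background alphabet is empty")
  withLocalSeed(seed, {
    chars <- sample(bg, length, replace = TRUE)
    positions <- integer(0)
    w <- nchar(word)
    tries <- 0L
    while (length(positions) < k) {
      tries <- tries + 1L
      if (tries > 1000L) stop("cannot place non-overlapping copies")
      pos <- sample.int(length - w + 1L, 1L)
      if (any(pos <= positions + w - 1L & pos + w - 1L >= positions)) next
      positions <- c(positions, pos)
    }
    positions <- sort(positions)
    for (pos in positions)
      chars[pos:(pos + w - 1L)] <- wordChars
    list(text = paste(chars, collapse = ""), positions = positions)
  })
}
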