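# evaluate expr with a local RNG state seeded by `seed`
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

sampleStarts <- function(boundaries) c(1L, head(boundaries, -1L) + 1L)

#' T-shuffling surrogate
#'
#' Replaces each series, independently per sample, by a uniform draw
#' without replacement from the sample's time range (distinct times, so the
#' no-duplicate-point invariant is respected). Per-series per-sample point
#' counts, labels, the period and sample boundaries are preserved; all
#' temporal structure is destroyed.
#'
#' @param data A [TData-class] object.
#' @param seed Integer seed; identical seeds give identical surrogates.
#' @return A surrogate [TData-class].
#' @export
shuffleTData <- function(data, seed) {
  stopifnot(is(data, "TData"))
  bounds <- sampleBoundaries(data)
  starts <- sampleStarts(bounds)
  withLocalSeed(seed, {
    series <- lapply(data@series, function(pts) {
      samp <- sampleIndexOf(pts, bounds)
      out <- integer(0)
      for (k in unique(samp)) {
        n <- sum(samp == k)
        L <- bounds[k] - starts[k] + 1L
        if (n > L) stop("series count exceeds sample length")
        out <- c(out, starts[k] - 1L + sample.int(L, n))
      }
      sort(out)
    })
    TData(series, period = data@period, sampleBoundaries = bounds)
  })
}

#' T-rotation surrogate
#'
#' Shifts each series, independently per sample, by one random circular
#' offset \code{dt} drawn uniformly from \code{1 .. L - 1} (\code{L} the
#' sample length): each point maps to \code{((t - 1 + dt) mod L) + 1}
#' relative to the sample origin. The circular inter-point interval
#' multiset of every series is preserved; samples of length 1 are left
#' unchanged.
#'
#' @inheritParams shuffleTData
#' @return A surrogate [TData-class].
#' @export
rotateTData <- function(data, seed) {
  stopifnot(is(data, "TData"))
  bounds <- sampleBoundaries(data)
  starts <- sampleStarts(bounds)
  withLocalSeed(seed, {
    series <- lapply(data@series, function(pts) {
      samp <- sampleIndexOf(pts, bounds)
      out <- integer(0)
      for (k in unique(samp)) {
        L <- bounds[k] - starts[k] + 1L
        p <- pts[samp == k]
        if (L > 1L) {
          dt <- sample.int(L - 1L, 1L)
          p <- ((p - starts[k] + dt) %% L) + starts[k]
        }
        out <- c(out, p)
      }
      sort(out)
    })
    TData(series, period = data@period, sampleBoundaries = bounds)
  })
}

countsByLength <- function(patterns) {
  if (!length(patterns)) return(integer(0))
  table(vapply(patterns, patternLength, 0L))
}

#' Monte Carlo validation of detected pattern counts
#'
#' Repeatedly randomizes the data with the chosen surrogate method, reruns
#' detection with byte-identical parameters, and compares the per-length
#' counts of distinct detected patterns in the original data with the mean
#' and (population) standard deviation across surrogates. The comparison
#' is descriptive — counts well above the surrogate mean plus one standard
#' deviation indicate structure beyond what chance produces at the chosen
#' significance level.
#'
#' @param data A [TData-class] object.
#' @param params [DetectionParams-class] used for both the original and
#'   every surrogate run.
#' @param method \code{"shuffle"} or \code{"rotation"}.
#' @param nRandomizations Number of surrogates (50 is a common choice).
#' @param seed Integer seed; surrogate i uses \code{seed + i}.
#' @return A [MonteCarloResult-class] object.
#' @export
monteCarloValidate <- function(data, params = detectionParams(),
                               method = c("shuffle", "rotation"),
                               nRandomizations = 50, seed = 1) {
  method <- match.arg(method)
  nRandomizations <- as.integer(nRandomizations)
  if (nRandomizations < 1L) stop("need at least one randomization")
  surrogate <- switch(method, shuffle = shuffleTData, rotation = rotateTData)
  obs <- countsByLength(detectTPatterns(data, params))
  tallies <- vector("list", nRandomizations)
  for (i in seq_len(nRandomizations))
    tallies[[i]] <- countsByLength(
      detectTPatterns(surrogate(data, seed + i), params))
  lens <- sort(unique(as.integer(c(names(obs),
                                   unlist(lapply(tallies, names))))))
  if (!length(lens)) lens <- integer(0)
  at <- function(cnt, l) { v <- cnt[as.character(l)]; ifelse(is.na(v), 0, v) }
  surro <- vapply(lens, function(l)
    vapply(tallies, at, 0, l = l), numeric(nRandomizations))
  surro <- matrix(surro, nrow = nRandomizations)
  mu <- if (length(lens)) colMeans(surro) else numeric(0)
  sdev <- if (length(lens))
    sqrt(colMeans(sweep(surro, 2L, mu)^2)) else numeric(0)
  new("MonteCarloResult", method = method,
      nRandomizations = nRandomizations, lengths = lens,
      observed = vapply(lens, at, 0, cnt = obs),
      surrogateMean = as.numeric(mu), surrogateSd = as.numeric(sdev))
}
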