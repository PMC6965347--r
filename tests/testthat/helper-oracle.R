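# Independent oracles, written naively and kept free of the package's
# optimized code paths.

# Exact P(X >= h) for independent Bernoulli trials by full enumeration of
# all 2^n outcomes (n <= ~16).
oracleTailGE <- function(probs, h) {
  n <- length(probs)
  if (h <= 0) return(1)
  if (h > n) return(0)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) >= h)
      total <- total + prod(ifelse(bits == 1L, probs, 1 - probs))
  }
  total
}

# Exact binomial upper tail by direct summation.
oracleBinomTail <- function(h, n, p) {
  if (h <= 0) return(1)
  if (h > n) return(0)
  sum(vapply(h:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), 0))
}

oracleSampleIndex <- function(t, boundaries) {
  vapply(t, function(x) which(boundaries >= x)[1L], integer(1))
}

# next-following distance of each left point to the right series (same
# sample), NA when none exists within dmax
oracleNextDistances <- function(a, b, boundaries, dmax) {
  sa <- oracleSampleIndex(a, boundaries)
  sb <- oracleSampleIndex(b, boundaries)
  vapply(seq_along(a), function(i) {
    cand <- b[b >= a[i] & sb == sa[i] & (b - a[i]) <= dmax]
    if (length(cand)) min(cand) - a[i] else NA_integer_
  }, integer(1))
}

# Full quadratic critical-interval scan, no pruning, pure R: evaluates
# every (d1, d2) pair of distinct next-following distances, counts hits as
# distinct right points, uses the renewal null with boundary truncation,
# applies the alpha/K selection control, and picks the minimizer with the
# same tie-breaks (smaller p, narrower, smaller d1).
oracleCIScan <- function(a, b, T, alpha = 0.005, nMin = 3,
                         boundaries = T, dmax = T - 1) {
  a <- as.integer(a); b <- as.integer(b)
  if (!length(a) || !length(b)) return(NULL)
  sa <- oracleSampleIndex(a, boundaries)
  sb <- oracleSampleIndex(b, boundaries)
  nextB <- vapply(seq_along(a), function(i) {
    cand <- b[b >= a[i] & sb == sa[i] & (b - a[i]) <= dmax]
    if (length(cand)) min(cand) else NA_integer_
  }, integer(1))
  d <- nextB - a
  ds <- sort(unique(d[!is.na(d)]))
  if (!length(ds)) return(NULL)
  K <- length(ds)
  rate <- length(b) / T
  best <- NULL
  for (d1 in ds) for (d2 in ds[ds >= d1]) {
    hitIdx <- which(!is.na(d) & d >= d1 & d <= d2)
    h <- length(unique(nextB[hitIdx]))
    if (h < nMin) next
    probs <- vapply(seq_along(a), function(i) {
      send <- boundaries[sa[i]]
      w <- min(a[i] + d2, send) - (a[i] + d1) + 1
      w <- max(0, min(w, d2 - d1 + 1))
      if (w == 0) 0 else (1 - rate)^d1 * (1 - (1 - rate)^w)
    }, 0)
    p <- if (length(a) <= 14) oracleTailGE(probs, h) else {
      # exact Poisson-binomial by full convolution
      f <- 1
      for (q in probs) f <- c(f * (1 - q), 0) + c(0, f * q)
      sum(f[(h + 1):length(f)])
    }
    if (p > alpha / K) next
    better <- is.null(best) || p < best$p ||
      (p == best$p && (d2 - d1 < best$d2 - best$d1 ||
                       (d2 - d1 == best$d2 - best$d1 && d1 < best$d1)))
    if (better) best <- list(d1 = d1, d2 = d2, p = p, h = h)
  }
  best
}

# ---- naive full detection oracle ------------------------------------------
# Patterns are carried as (labels, terminal-time matrix, max node p); all
# steps (CI scan, pairing, zero-gap point-reuse rule, competition) are
# re-derived here from the definitions, independently of the package's
# optimized implementation.

oracleKey <- function(labels, tm)
  paste(paste(labels, collapse = " "), paste(t(tm), collapse = ","),
        sep = "|")

oracleMatch <- function(np, nq, compatible) {
  matchQ <- integer(nq)
  tryA <- function(i, seen) {
    for (j in seq_len(nq)) {
      if (seen[j] || !compatible(i, j)) next
      seen[j] <- TRUE
      if (matchQ[j] == 0L || Recall(matchQ[j], seen)) {
        matchQ[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  all(vapply(seq_len(np), function(i) tryA(i, logical(nq)), logical(1)))
}

oracleCompete <- function(pats) {
  if (length(pats) <= 1L) return(pats)
  keys <- vapply(pats, function(p) oracleKey(p$labels, p$tm), "")
  keep <- rep(TRUE, length(pats))
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    best <- idx[which.min(vapply(pats[idx], function(p) p$maxP, 0))]
    keep[setdiff(idx, best)] <- FALSE
  }
  live <- which(keep)
  drop <- rep(FALSE, length(pats))
  timedSub <- function(labX, tX, labY, tY) {
    i <- 1L
    for (j in seq_along(labY)) {
      if (i > length(labX)) return(TRUE)
      if (labX[i] == labY[j] && tX[i] == tY[j]) i <- i + 1L
    }
    i > length(labX)
  }
  for (i in live) for (j in live) {
    if (i == j) next
    P <- pats[[i]]; Q <- pats[[j]]
    if (nrow(P$tm) != nrow(Q$tm)) next
    if (length(P$labels) >= length(Q$labels)) next
    ok <- oracleMatch(nrow(P$tm), nrow(Q$tm), function(pi, qj)
      timedSub(P$labels, P$tm[pi, ], Q$labels, Q$tm[qj, ]))
    if (ok) { drop[i] <- TRUE; break }
  }
  pats[keep & !drop]
}

oracleDetect <- function(data, params) {
  T <- periodLength(data)
  bounds <- sampleBoundaries(data)
  alpha <- params@alpha; nMin <- params@nMin
  terminals <- lapply(eventLabels(data), function(lab)
    list(labels = lab, tm = matrix(seriesPoints(data, lab), ncol = 1L),
         maxP = 0))
  pats <- list()
  for (pass in seq_len(params@maxLevels)) {
    ws <- c(terminals, pats)
    cand <- list()
    seen <- c(vapply(pats, function(p) oracleKey(p$labels, p$tm), ""))
    for (i in seq_along(ws)) for (j in seq_along(ws)) {
      if (i == j) next
      P <- ws[[i]]; Q <- ws[[j]]
      if (length(P$labels) + length(Q$labels) > params@maxLength) next
      lEnd <- P$tm[, ncol(P$tm)]; lStart <- P$tm[, 1L]
      rStart <- Q$tm[, 1L]; rEnd <- Q$tm[, ncol(Q$tm)]
      ci <- oracleCIScan(sort(lEnd), rStart, T, alpha = alpha,
                         nMin = nMin, boundaries = bounds)
      if (is.null(ci)) next
      sa <- oracleSampleIndex(lEnd, bounds)
      sb <- oracleSampleIndex(rStart, bounds)
      used <- rep(FALSE, nrow(Q$tm))
      li <- ri <- integer(0)
      for (x in seq_along(lEnd)) {
        for (y in seq_len(nrow(Q$tm))) {
          if (used[y]) next
          gap <- rStart[y] - lEnd[x]
          if (gap >= ci$d1 && gap <= ci$d2 && sa[x] == sb[y]) {
            # reject pairings that reuse the same (label, time) point
            pl <- paste(P$labels, P$tm[x, ])
            ql <- paste(Q$labels, Q$tm[y, ])
            if (length(intersect(pl, ql))) next
            used[y] <- TRUE
            li <- c(li, x); ri <- c(ri, y)
            break
          }
        }
      }
      if (length(li) < nMin) next
      tm <- cbind(P$tm[li, , drop = FALSE], Q$tm[ri, , drop = FALSE])
      labels <- c(P$labels, Q$labels)
      key <- oracleKey(labels, tm)
      if (key %in% seen) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- list(labels = labels, tm = tm,
                                        maxP = max(P$maxP, Q$maxP, ci$p))
    }
    if (!length(cand)) break
    surv <- oracleCompete(c(pats, cand))
    if (identical(vapply(surv, function(p) oracleKey(p$labels, p$tm), ""),
                  vapply(pats, function(p) oracleKey(p$labels, p$tm), "")))
      break
    pats <- surv
  }
  sort(vapply(pats, function(p) oracleKey(p$labels, p$tm), ""))
}
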