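# Shared fixture builders (all data generated in code; no files).

# Three-terminal pattern A -> B -> C with gaps 5 and 7 planted k times in
# T = 1e4, plus 10 extra uniform noise points per involved series and 5
# pure-noise background series of 10 points each.
plantedTripleData <- function(k, seed, noisePerInvolved = 10L,
                              nNoiseSeries = 5L) {
  noise <- generateNoiseTData(nNoiseSeries, 10, 10000, seed)
  res <- plantPattern(noise,
                      patternTemplate(c("A", "B", "C"), list(5L, 7L), k),
                      seed = seed + 1000L)
  d <- res$data
  if (noisePerInvolved > 0L) {
    set.seed(seed + 2000L)
    for (lab in c("A", "B", "C")) {
      pts <- d@series[[lab]]
      extra <- setdiff(sample.int(10000, 6L * noisePerInvolved),
                       pts)[seq_len(noisePerInvolved)]
      d@series[[lab]] <- sort(as.integer(c(pts, extra)))
    }
  }
  list(data = d, truth = res$truth)
}

# does a detected pattern list recover every planted (A, B, C) triple
# inside a single pattern, using the planted points themselves?
tripleRecovered <- function(patterns, data, truth) {
  for (p in patterns) {
    tq <- patternTerminals(p)
    if (!tpattern:::isSubsequence(c("A", "B", "C"), tq)) next
    tt <- tpattern:::patternTerminalTimes(p, data@series)
    ia <- which(tq == "A"); ib <- which(tq == "B"); ic <- which(tq == "C")
    ok <- apply(truth, 1L, function(tr)
      any(apply(tt, 1L, function(row)
        any(row[ia] == tr[1L]) && any(row[ib] == tr[2L]) &&
          any(row[ic] == tr[3L]))))
    if (all(ok)) return(TRUE)
  }
  FALSE
}

# small random TData for property loops
randomMicroTData <- function(seed, nSeries = 3L, maxPoints = 8L, T = 60L) {
  withr_seed <- seed  # deterministic per seed
  set.seed(withr_seed)
  series <- lapply(seq_len(nSeries), function(i)
    sort(sample.int(T, sample.int(maxPoints, 1L))))
  names(series) <- letters[seq_len(nSeries)]
  TData(series, period = T)
}
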