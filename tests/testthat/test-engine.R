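mkOcc <- function(starts, ends) cbind(start = as.integer(starts),
                                      end = as.integer(ends))

test_that("greedy pairing joins each left to the earliest eligible right", {
  l <- mkOcc(c(5, 20), c(5, 20)); r <- mkOcc(c(9, 26), c(9, 26))
  pr <- pairOccurrences(l, r, 3, 6)
  expect_equal(unname(pr$occ), cbind(c(5L, 20L), c(9L, 26L)))

  # contention: earliest left wins the only right
  l2 <- mkOcc(c(5, 6), c(5, 6)); r2 <- mkOcc(9, 9)
  pr2 <- pairOccurrences(l2, r2, 3, 4)
  expect_equal(unname(pr2$occ), cbind(5L, 9L))

  # gap outside the interval: no pairing
  pr3 <- pairOccurrences(mkOcc(5, 5), mkOcc(9, 9), 5, 6)
  expect_equal(nrow(pr3$occ), 0L)

  # rights are never reused
  l4 <- mkOcc(c(1, 2, 3), c(1, 2, 3)); r4 <- mkOcc(c(4, 5), c(4, 5))
  pr4 <- pairOccurrences(l4, r4, 1, 5)
  expect_equal(length(unique(pr4$rightMap)), length(pr4$rightMap))
})

test_that("planted pair in silence is recovered with its exact interval", {
  base <- TData(setNames(lapply(1:2, function(i) integer()), c("A", "B")),
                period = 10000)
  res <- plantPattern(base, patternTemplate(c("A", "B"), list(5L), 6L),
                      seed = 2)
  pats <- detectTPatterns(res$data, detectionParams())
  expect_length(pats, 1L)
  p <- pats[[1L]]
  expect_equal(patternTerminals(p), c("A", "B"))
  expect_equal(c(p@ci@d1, p@ci@d2), c(5L, 5L))
  expect_equal(nOccurrences(p), 6L)
  expect_true(isTRUE(verifyTPattern(p, res$data, detectionParams())))
})

test_that("planted three-terminal pattern survives noise", {
  bd <- plantedTripleData(4, seed = 5)
  pats <- detectTPatterns(bd$data, detectionParams())
  expect_true(tripleRecovered(pats, bd$data, bd$truth))
  ok <- vapply(pats, function(p)
    isTRUE(verifyTPattern(p, bd$data, detectionParams())), logical(1))
  expect_true(all(ok))
})

test_that("every reported pattern passes independent re-verification", {
  for (s in c(3, 9)) {
    td <- generateNoiseTData(6, 12, 10000, seed = s)
    params <- detectionParams()
    pats <- detectTPatterns(td, params)
    for (p in pats) expect_true(isTRUE(verifyTPattern(p, td, params)))
  }
})

test_that("the verifier rejects corrupted patterns", {
  bd <- plantedTripleData(4, seed = 5)
  params <- detectionParams()
  pats <- detectTPatterns(bd$data, params)
  p <- pats[[1L]]
  # corrupt an occurrence end: stored span no longer matches children
  bad <- p
  bad@occurrences[1L, 2L] <- bad@occurrences[1L, 2L] + 1L
  expect_false(isTRUE(verifyTPattern(bad, bd$data, params)))
  # remove a raw point: terminal conservation broken
  mut <- bd$data
  lab <- patternTerminals(p)[1L]
  mut@series[[lab]] <- mut@series[[lab]][-1L]
  expect_false(isTRUE(verifyTPattern(p, mut, params)))
})

test_that("detection equals the naive enumeration oracle on micro data", {
  params <- detectionParams(nMin = 2, maxLength = 6, maxLevels = 5)
  for (s in 1:12) {
    td <- randomMicroTData(s)
    got <- detectTPatterns(td, params)
    gotKeys <- sort(vapply(got, function(p)
      oracleKey(patternTerminals(p),
                tpattern:::patternTerminalTimes(p, td@series)), ""))
    expect_equal(gotKeys, oracleDetect(td, params), info = paste("seed", s))
  }
})

test_that("detection is deterministic", {
  td <- generateNoiseTData(5, 12, 5000, seed = 4)
  p1 <- detectTPatterns(td, detectionParams())
  p2 <- detectTPatterns(td, detectionParams())
  expect_identical(vapply(p1, tpattern:::patternKey, ""),
                   vapply(p2, tpattern:::patternKey, ""))
})

test_that("relaxing alpha or nMin never loses a detected pattern", {
  bd <- plantedTripleData(3, seed = 8)
  strict <- detectTPatterns(bd$data, detectionParams(alpha = 0.001))
  loose <- detectTPatterns(bd$data, detectionParams(alpha = 0.005))
  inLoose <- function(p, set) {
    tt <- tpattern:::patternTerminalTimes(p, bd$data@series)
    any(vapply(set, function(q) {
      tq <- tpattern:::patternTerminalTimes(q, bd$data@series)
      any(apply(tq, 1L, function(row)
        tpattern:::timedSubseq(patternTerminals(p), tt[1L, ],
                               patternTerminals(q), row)))
    }, logical(1)))
  }
  # every strict detection survives, possibly absorbed into a larger one
  for (p in strict) expect_true(inLoose(p, loose))
})

test_that("completeness competition drops redundant sub-patterns", {
  ciX <- CriticalInterval(2, 4, 1e-5, 4L)
  # Q = (A B C): 4 occurrences; P = (A B) realized exactly inside them
  P <- tpattern:::newTPattern("A", "B", ciX,
                              mkOcc(c(10, 50, 90, 130), c(14, 54, 94, 134)))
  Q <- tpattern:::newTPattern(P, "C", ciX,
                              mkOcc(c(10, 50, 90, 130), c(20, 60, 100, 140)))
  expect_length(completenessCompetition(list(P, Q)), 1L)
  expect_equal(patternTerminals(completenessCompetition(list(P, Q))[[1L]]),
               c("A", "B", "C"))

  # extra instances protect the shorter pattern
  P7 <- tpattern:::newTPattern("A", "B", ciX,
                               mkOcc(seq(10, 250, 40), seq(14, 254, 40)))
  expect_length(completenessCompetition(list(P7, Q)), 2L)

  # identical terminals and occurrences, different shapes: one survivor,
  # the one with the smaller maximal node p
  ciGood <- CriticalInterval(1, 1, 1e-8, 4L)
  ciBad <- CriticalInterval(1, 1, 1e-3, 4L)
  occ3 <- mkOcc(c(10, 50), c(20, 60))
  AB <- tpattern:::newTPattern("A", "B", ciGood, mkOcc(c(10, 50), c(14, 54)))
  BC <- tpattern:::newTPattern("B", "C", ciGood, mkOcc(c(14, 54), c(20, 60)))
  left <- tpattern:::newTPattern(AB, "C", ciBad, occ3)
  right <- tpattern:::newTPattern("A", BC, ciGood, occ3)
  surv <- completenessCompetition(list(left, right))
  expect_length(surv, 1L)
  expect_equal(maxNodeP(surv[[1L]]), 1e-8)
})

test_that("point-level competition does not let junk absorb real patterns", {
  series <- list(A = c(10L, 50L), B = c(14L, 54L), C = c(20L, 60L),
                 X = c(5L, 45L), Y = c(30L, 70L))
  ciX <- CriticalInterval(0, 50, 1e-5, 2L)
  real <- tpattern:::newTPattern("A", "B", ciX, mkOcc(c(10, 50), c(14, 54)),
                                 leftMap = 1:2, rightMap = 1:2)
  # junk spans contain the real occurrences but use X, A, B, Y elsewhere
  junkAB <- tpattern:::newTPattern("A", "B", ciX, mkOcc(c(10, 50), c(14, 54)),
                                   leftMap = 1:2, rightMap = 1:2)
  junkXY <- tpattern:::newTPattern(
    tpattern:::newTPattern("X", junkAB, ciX, mkOcc(c(5, 45), c(14, 54)),
                           leftMap = 1:2, rightMap = 1:2),
    "Y", ciX, mkOcc(c(5, 45), c(30, 70)), leftMap = 1:2, rightMap = 1:2)
  # span-level: real (A B) is absorbed; point-level: it is too, because
  # the junk really does use the same A and B points
  expect_length(completenessCompetition(list(real, junkXY), series), 1L)

  # now junk built on different A/B points (via an alternative series
  # layout) must NOT absorb the real pattern
  series2 <- list(A = c(10L, 11L, 50L, 51L), B = c(14L, 15L, 54L, 55L),
                  X = c(5L, 45L))
  realP <- tpattern:::newTPattern("A", "B", ciX,
                                  mkOcc(c(10, 50), c(14, 54)),
                                  leftMap = c(1L, 3L), rightMap = c(1L, 3L))
  other <- tpattern:::newTPattern(
    "X", tpattern:::newTPattern("A", "B", ciX, mkOcc(c(11, 51), c(15, 55)),
                                leftMap = c(2L, 4L), rightMap = c(2L, 4L)),
    ciX, mkOcc(c(5, 45), c(15, 55)), leftMap = 1:2, rightMap = 1:2)
  expect_length(completenessCompetition(list(realP, other), series2), 2L)
})

test_that("bursts are found at the optimal gap threshold and verified", {
  td <- TData(list(x = c(10L, 11L, 12L, 500L, 800L, 801L, 803L)),
              period = 10000)
  b <- detectTBursts("x", td, detectionParams())
  expect_length(b, 1L)
  expect_true(isBurst(b[[1L]]))
  expect_equal(unname(occurrences(b[[1L]])),
               cbind(c(10L, 800L), c(12L, 803L)))
  expect_true(isTRUE(verifyTPattern(b[[1L]], td, detectionParams())))
})

test_that("a lone tight doublet on a huge period is a significant burst", {
  td <- TData(list(x = c(5L, 6L)), period = 1000000)
  b <- detectTBursts("x", td, detectionParams())
  expect_length(b, 1L)
  expect_equal(unname(occurrences(b[[1L]])), cbind(5L, 6L))
  # exact tail: two trials, next-point hit probability (n-1)/T per unit
  # over a 2-unit window
  p0 <- 1 - (1 - 1e-6)^2
  expect_equal(b[[1L]]@ci@pValue, oracleBinomTail(1, 2, p0),
               tolerance = 1e-9)
})

test_that("uniform series yield no bursts", {
  fp <- 0L
  for (s in 1:200) {
    td <- generateNoiseTData(1, 20, 10000, seed = s)
    if (length(detectTBursts("noise_1", td, detectionParams())))
      fp <- fp + 1L
  }
  expect_lte(fp, 2L)  # >= 99% of replicates silent
})

test_that("series with fewer than two points cannot burst", {
  td <- TData(list(x = 5L, y = integer()), period = 100)
  expect_length(detectTBursts("x", td, detectionParams()), 0L)
  expect_length(detectTBursts("y", td, detectionParams()), 0L)
})

test_that("burst mode nests bursts inside larger patterns", {
  # a triplet burst of x precedes each of 4 occurrences of y by 10 units
  x <- as.integer(c(100, 101, 102, 1100, 1101, 1102,
                    2100, 2101, 2102, 3100, 3101, 3102))
  y <- as.integer(c(112, 1112, 2112, 3112))
  td <- TData(list(x = x, y = y), period = 10000)
  pats <- detectTPatterns(td, detectionParams(mode = "burst"))
  nested <- Filter(function(p) !isBurst(p) &&
                     identical(patternTerminals(p), c("x", "x", "y")),
                   pats)
  expect_gte(length(nested), 1L)
  # the burst survives as the left branch of the larger pattern (the
  # stand-alone burst is correctly absorbed: same points, same count)
  expect_true(is(nested[[1L]]@left, "TPattern") && isBurst(nested[[1L]]@left))
  expect_true(isTRUE(verifyTPattern(nested[[1L]], td, detectionParams())))
})

test_that("empty data yields an empty result", {
  expect_length(detectTPatterns(TData(list(), period = 10),
                                detectionParams()), 0L)
})
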