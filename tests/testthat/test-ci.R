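test_that("null window probability matches closed form and Monte Carlo", {
  expect_equal(nullProbWindow(1, 1000, 1), 0.001)
  expect_equal(nullProbWindow(0, 100, 50), 0)
  expect_equal(nullProbWindow(100, 100, 3), 1)
  # monotone in both arguments
  expect_true(all(diff(nullProbWindow(1:50, 100, 5)) >= 0))
  expect_true(all(diff(nullProbWindow(10, 100, 0:20)) >= 0))
  expect_error(nullProbWindow(101, 100, 2), "nB")

  # uniform-placement Monte Carlo oracle: 389 points on 10103 units,
  # window of width 2 (hypergeometric draw of the window occupancy)
  set.seed(424242)
  draws <- stats::rhyper(1e5, 389, 10103 - 389, 2)
  freq <- mean(draws >= 1)
  se <- sqrt(freq * (1 - freq) / 1e5)
  expect_lt(abs(nullProbWindow(389, 10103, 2) - freq), 3 * se)
})

test_that("ciPValue reproduces the exact binomial tail on known cases", {
  r <- ciPValue(c(10, 30, 50), c(13, 33, 70), T = 100, d1 = 3, d2 = 3)
  expect_equal(r$nHits, 2L)
  expect_equal(r$pValue, 3 * 0.03^2 * 0.97 + 0.03^3)

  # no hits: tail at zero is 1
  r0 <- ciPValue(c(10, 30), c(90), T = 100, d1 = 1, d2 = 2)
  expect_equal(r0$nHits, 0L)
  expect_equal(r0$pValue, 1)

  # saturated null: every unit occupied
  rs <- ciPValue(c(2, 5), 1:100, T = 100, d1 = 0, d2 = 3)
  expect_equal(rs$nHits, 2L)
  expect_equal(rs$pValue, 1)

  # empty series degenerate
  expect_equal(ciPValue(integer(), c(1, 2), 10, 0, 1),
               list(pValue = 1, nHits = 0L))
})

test_that("ciPValue equals exhaustive enumeration for small left series", {
  set.seed(11)
  for (rep in 1:25) {
    T <- 80L
    na <- sample(1:6, 1)
    nb <- sample(1:10, 1)
    a <- sort(sample.int(T, na)); b <- sort(sample.int(T, nb))
    d1 <- sample(0:5, 1); d2 <- d1 + sample(0:6, 1)
    r <- ciPValue(a, b, T, d1, d2)
    hits <- sum(vapply(a, function(x) any(b >= x + d1 & b <= x + d2),
                       logical(1)))
    probs <- vapply(a, function(x) {
      w <- min(x + d2, T) - (x + d1) + 1
      w <- max(0, min(w, d2 - d1 + 1))
      if (w == 0) 0 else 1 - (1 - nb / T)^w
    }, 0)
    expect_equal(r$nHits, hits)
    expect_equal(r$pValue, oracleTailGE(probs, hits), tolerance = 1e-12)
  }
})

test_that("exact tail is monotone in the hit count", {
  probs <- c(0.02, 0.05, 0.1, 0.02, 0.3)
  tails <- vapply(0:5, function(h) tpattern:::tailGE(probs, h), 0)
  expect_true(all(diff(tails) <= 0))
  expect_equal(tails[1], 1)
})

test_that("capped dynamic program matches enumeration for unequal trials", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    probs <- runif(n, 0, 0.6)
    h <- sample.int(n, 1)
    expect_equal(tpattern:::tailGE(probs, h), oracleTailGE(probs, h),
                 tolerance = 1e-10)
  }
})

test_that("interval search returns the brute-force optimum on planted data", {
  ci <- detectCriticalInterval(c(10, 30, 50), c(13, 33, 53), T = 1000,
                               detectionParams())
  expect_s4_class(ci, "CriticalInterval")
  expect_equal(c(ci@d1, ci@d2), c(3L, 3L))
  expect_equal(ci@nHits, 3L)
  o <- oracleCIScan(c(10, 30, 50), c(13, 33, 53), 1000)
  expect_equal(ci@pValue, o$p, tolerance = 1e-12)
})

test_that("interval search agrees with the naive quadratic oracle", {
  set.seed(21)
  for (rep in 1:40) {
    T <- 500L
    a <- sort(sample.int(T, sample(3:12, 1)))
    b <- sort(sample.int(T, sample(3:12, 1)))
    nMin <- sample(2:3, 1)
    ci <- detectCriticalInterval(a, b, T, detectionParams(nMin = nMin))
    o <- oracleCIScan(a, b, T, nMin = nMin)
    if (is.null(o)) {
      expect_null(ci)
    } else {
      expect_false(is.null(ci))
      expect_equal(c(ci@d1, ci@d2, ci@nHits), c(o$d1, o$d2, o$h))
      expect_equal(ci@pValue, o$p, tolerance = 1e-9)
    }
  }
})

test_that("returned intervals always satisfy the significance contract", {
  set.seed(77)
  for (rep in 1:30) {
    td <- generateNoiseTData(2, 15, 2000, seed = rep)
    params <- detectionParams(nMin = 3)
    ci <- detectCriticalInterval(seriesPoints(td, "noise_1"),
                                 seriesPoints(td, "noise_2"),
                                 periodLength(td), params)
    if (!is.null(ci)) {
      expect_lte(ci@pValue, params@alpha)
      expect_gte(ci@nHits, params@nMin)
      expect_lte(ci@nHits, length(seriesPoints(td, "noise_1")))
      expect_true(ci@d1 >= 0 && ci@d2 >= ci@d1)
    }
  }
})

test_that("fixed [1,1] mode detects planted adjacency and nothing else", {
  # 'o' followed by 'f' planted 4 times in a background without o or f
  g <- generateTextWithPlants(400, word = "of", k = 4, seed = 3)
  td <- sequenceToTData(g$text)
  ci <- detectCriticalInterval(seriesPoints(td, "o"), seriesPoints(td, "f"),
                               periodLength(td),
                               detectionParams(mode = "fixed11"))
  expect_false(is.null(ci))
  expect_equal(c(ci@d1, ci@d2), c(1L, 1L))
  expect_equal(ci@nHits, 4L)
  # reversed direction: f never directly precedes o
  expect_null(detectCriticalInterval(seriesPoints(td, "f"),
                                     seriesPoints(td, "o"),
                                     periodLength(td),
                                     detectionParams(mode = "fixed11")))
})

test_that("windows never cross sample boundaries", {
  # b follows a at distance 2 within sample 1 three times; a fourth "a"
  # sits at a sample end with its "b" in the next sample, which must not
  # count as a hit
  a <- c(10L, 30L, 50L, 100L)
  b <- c(12L, 32L, 52L, 101L)
  r <- ciPValue(a, b, T = 200, d1 = 2, d2 = 2, boundaries = c(100L, 200L))
  expect_equal(r$nHits, 3L)
  rAll <- ciPValue(a, b, T = 200, d1 = 1, d2 = 2,
                   boundaries = c(100L, 200L))
  expect_equal(rAll$nHits, 3L)
  rOne <- ciPValue(a, b, T = 200, d1 = 1, d2 = 2)
  expect_equal(rOne$nHits, 4L)
})

test_that("detection parameter validation enforces documented ranges", {
  expect_error(detectionParams(alpha = 0), "alpha")
  expect_error(detectionParams(nMin = 1), "nMin")
  expect_error(detectionParams(maxLength = 1), "maxLength")
  expect_error(detectionParams(mode = "bogus"))
  p <- detectionParams()
  expect_equal(p@alpha, 0.005)
  expect_equal(p@nMin, 3L)
})
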