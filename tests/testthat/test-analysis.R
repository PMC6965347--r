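mk <- function(left, right, ci, occ, ...)
  tpattern:::newTPattern(left, right, ci, occ, ...)
ciX <- CriticalInterval(1, 3, 1e-4, 4L)

test_that("pattern statistics count actors, switches and spans", {
  inner <- mk("x,b,pick", "y,b,take", ciX,
              cbind(c(5L, 20L), c(7L, 22L)))
  p <- mk(inner, "x,e,look", ciX, cbind(c(5L, 20L), c(9L, 26L)))
  st <- patternStats(p)
  expect_equal(st$m, 3L)
  expect_equal(st$actors, 2L)
  expect_equal(st$switches, 2L)
  expect_equal(st$n, 2L)
  expect_equal(st$meanSpan, mean(c(4, 6)))
  expect_equal(st$minSpan, 4L)
  expect_equal(st$maxSpan, 6L)

  single <- mk("x,b,pick", "x,e,pick", ciX, cbind(5L, 9L))
  expect_equal(patternStats(single)$switches, 0L)
  expect_equal(patternStats(single)$actors, 1L)

  # labels outside the convention are excluded from actor statistics
  plain <- mk("A", "B", ciX, cbind(5L, 9L))
  expect_equal(patternStats(plain)$actors, 0L)
})

test_that("selection filters by content, order and actors", {
  pABC <- mk(mk("A", "B", ciX, cbind(c(1L, 10L), c(3L, 12L))), "C", ciX,
             cbind(c(1L, 10L), c(5L, 14L)))
  pCBA <- mk(mk("C", "B", ciX, cbind(c(1L, 10L), c(3L, 12L))), "A", ciX,
             cbind(c(1L, 10L), c(5L, 14L)))
  pats <- list(pABC, pCBA)

  expect_equal(selectPatterns(pats, c("A", "C"), ordered = TRUE), list(pABC))
  expect_length(selectPatterns(pats, c("A", "C"), ordered = FALSE), 2L)
  expect_identical(selectPatterns(pats), pats)      # empty filter: identity
  expect_length(selectPatterns(pats, multiActorOnly = TRUE), 0L)
  expect_error(selectPatterns(pats, "Z"), "unknown")

  # idempotence and commutativity
  f1 <- selectPatterns(selectPatterns(pats, "A"), "A")
  expect_identical(f1, selectPatterns(pats, "A"))
  ab <- selectPatterns(selectPatterns(pats, "A"), "B")
  ba <- selectPatterns(selectPatterns(pats, "B"), "A")
  expect_identical(ab, ba)
})

test_that("inventory reports minimal first-appearance depth", {
  p <- mk(mk("A", "B", ciX, cbind(1L, 3L)), "C", ciX, cbind(1L, 5L))
  inv <- eventTypeInventory(list(p))
  expect_equal(inv$firstLevel[inv$label == "A"], 2L)
  expect_equal(inv$firstLevel[inv$label == "B"], 2L)
  expect_equal(inv$firstLevel[inv$label == "C"], 1L)

  expect_equal(nrow(eventTypeInventory(list())), 0L)

  # minimum across patterns
  shallow <- mk("A", "D", ciX, cbind(1L, 4L))
  inv2 <- eventTypeInventory(list(p, shallow))
  expect_equal(inv2$firstLevel[inv2$label == "A"], 1L)
})

test_that("pattern table export is stable and round-computable", {
  bd <- plantedTripleData(4, seed = 5)
  pats <- detectTPatterns(bd$data, detectionParams())
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  tab <- exportPatternTable(pats, f1)
  exportPatternTable(pats, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  back <- utils::read.delim(f1)
  expect_equal(nrow(back), length(pats))
  expect_equal(back$m, vapply(pats, patternLength, 0L))
  expect_equal(back$n, vapply(pats, nOccurrences, 0L))
  # stats recomputed from the table equal the in-memory stats
  inMem <- do.call(rbind, lapply(pats, patternStats))
  expect_equal(back$actors, inMem$actors)
  expect_equal(back$switches, inMem$switches)

  empty <- withr::local_tempfile()
  exportPatternTable(list(), empty)
  expect_equal(length(readLines(empty)), 1L)       # header only
})

test_that("diagram export writes a tree and a verifiable point-map", {
  base <- TData(list(A = integer(), B = integer()), period = 2000)
  res <- plantPattern(base, patternTemplate(c("A", "B"), list(4L), 3L),
                      seed = 1)
  pats <- detectTPatterns(res$data, detectionParams())
  p <- pats[[1L]]
  dot <- withr::local_tempfile(fileext = ".dot")
  js <- withr::local_tempfile(fileext = ".json")
  pm <- exportPatternDiagram(p, res$data, dot, js)

  lines <- readLines(dot)
  expect_true(any(grepl("digraph", lines)))
  expect_equal(sum(grepl("shape=ellipse", lines)), 1L)  # one internal node
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), 2L)

  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$terminals, c("A", "B"))
  # every connection's gaps re-verify against the critical interval
  for (conn in pm$connections) {
    gaps <- diff(conn)
    expect_true(all(gaps >= p@ci@d1 & gaps <= p@ci@d2))
  }
  expect_equal(length(pm$connections), nOccurrences(p))

  expect_error(exportPatternDiagram(p, TData(list(zz = 1L)), NULL, NULL),
               "absent")
})
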