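test_that("buildHistogram bins events half-open with a closed last bin", {
  spec <- binSpec(1, 1e4, 2)
  expect_equal(binCounts(buildHistogram(c(10, 50, 1000), spec)), c(2, 1))
  # empty input
  expect_equal(binCounts(buildHistogram(numeric(0), spec)), c(0, 0))
  # an event exactly at an interior edge goes to the upper bin
  expect_equal(binCounts(buildHistogram(100, spec)), c(0, 1))
  # the top edge is included in the last bin; out-of-range events are
  # dropped and recorded in the label
  h <- buildHistogram(c(0.5, 1e4, 2e4), spec)
  expect_equal(binCounts(h), c(0, 1))
  expect_match(histLabel(h), "2 outside range dropped")
  expect_equal(sum(binCounts(h)), 1)
})

test_that("buildHistogram rejects invalid specs and events", {
  expect_error(binSpec(10, 1), "lo < hi")
  expect_error(binSpec(0, 10, scale = "log10"), "lo > 0")
  expect_error(buildHistogram(c(1, NA), binSpec()), "finite")
  expect_error(buildHistogram(-1, binSpec()), ">= 0")
})

test_that("truncateAtThreshold keeps bins at/above threshold and drops straddlers", {
  h <- toyHistogram(threshold = 10)
  tr <- truncateAtThreshold(h)
  expect_equal(binEdges(tr), c(10, 100, 1000))
  expect_equal(binCounts(tr), c(7, 9))
  # threshold 0 is a no-op
  expect_equal(truncateAtThreshold(toyHistogram()), toyHistogram())
  # a straddled bin is dropped entirely
  tr50 <- truncateAtThreshold(toyHistogram(threshold = 50))
  expect_equal(binEdges(tr50), c(100, 1000))
  expect_equal(binCounts(tr50), 9)
  # idempotence
  expect_equal(truncateAtThreshold(tr50), tr50)
  # threshold above all edges: warning + empty histogram
  expect_warning(empty <- truncateAtThreshold(toyHistogram(threshold = 1e6)),
                 "above all bin edges")
  expect_length(binCounts(empty), 0)
  expect_equal(truncateAtThreshold(empty), empty)
})

test_that("hellinger matches hand-computed values in both modes", {
  a <- fluorescenceHistogram(c(1, 10, 100), c(4, 0))
  b <- fluorescenceHistogram(c(1, 10, 100), c(0, 4))
  expect_identical(hellinger(a, a), 0)
  expect_identical(hellinger(a, a, "probability"), 0)
  expect_equal(hellinger(a, b, "count"), 2 * sqrt(2))
  expect_equal(hellinger(a, b, "probability"), 1)
  # errors: mismatched binning and undefined normalization
  c3 <- fluorescenceHistogram(c(1, 50, 100), c(1, 1))
  expect_error(hellinger(a, c3), "identical bin edges")
  z <- fluorescenceHistogram(c(1, 10, 100), c(0, 0))
  expect_error(hellinger(z, z, "probability"), "all-zero")
})

test_that("probability-mode hellinger is a bounded metric; count mode dominates at unit totals", {
  set.seed(42)
  for (i in 1:40) {
    h1 <- randomHistogram(); h2 <- randomHistogram(); h3 <- randomHistogram()
    d12 <- hellinger(h1, h2, "probability")
    d21 <- hellinger(h2, h1, "probability")
    expect_gte(d12, 0)
    expect_lte(d12, 1 + 1e-12)
    expect_equal(d12, d21)
    # triangle inequality
    expect_lte(d12, hellinger(h1, h3, "probability") +
                     hellinger(h3, h2, "probability") + 1e-12)
    # identity of indiscernibles
    if (d12 < 1e-12) expect_equal(binCounts(h1) / sum(binCounts(h1)),
                                  binCounts(h2) / sum(binCounts(h2)))
    # unit-normalized count mode = sqrt(2) * probability mode
    u1 <- fluorescenceHistogram(binEdges(h1), binCounts(h1) / sum(binCounts(h1)))
    u2 <- fluorescenceHistogram(binEdges(h2), binCounts(h2) / sum(binCounts(h2)))
    expect_gte(hellinger(u1, u2, "count") + 1e-12, d12)
  }
})

test_that("alignBins refines onto common edges conserving mass on the log scale", {
  # identical binnings pass through unchanged
  h1 <- toyHistogram(); h2 <- toyHistogram(c(1, 2, 3))
  al <- alignBins(h1, h2)
  expect_identical(al$h1, h1)
  # a [10,1000) bin split at 100 gives equal log-width halves
  coarse <- fluorescenceHistogram(c(10, 1000), 10)
  fine <- fluorescenceHistogram(c(10, 100, 1000), c(3, 4))
  al <- alignBins(coarse, fine)
  expect_equal(binEdges(al$h1), c(10, 100, 1000))
  expect_equal(binCounts(al$h1), c(5, 5))
  expect_equal(binCounts(al$h2), c(3, 4))
  # disjoint ranges fail
  expect_error(alignBins(fluorescenceHistogram(c(1, 10), 1),
                         fluorescenceHistogram(c(100, 1000), 1)),
               "disjoint")
})

test_that("alignBins conserves overlap mass for random partial overlaps", {
  set.seed(7)
  for (i in 1:20) {
    e1 <- 10^sort(runif(5, 0, 3)); e1 <- e1 * (1 + 1e-6 * seq_along(e1))
    e2 <- 10^sort(runif(4, 0.5, 3.5)); e2 <- e2 * (1 + 1e-6 * seq_along(e2))
    h1 <- fluorescenceHistogram(e1, rpois(4, 10))
    h2 <- fluorescenceHistogram(e2, rpois(3, 10))
    lo <- max(e1[1], e2[1]); hi <- min(e1[5], e2[4])
    if (lo >= hi) next
    al <- alignBins(h1, h2)
    expect_equal(binEdges(al$h1), binEdges(al$h2))
    # overlap mass of each input, computed independently by log-fraction
    overlapMass <- function(h) {
      le <- log10(binEdges(h)); ct <- binCounts(h)
      s <- 0
      for (j in seq_along(ct)) {
        a <- max(le[j], log10(lo)); b <- min(le[j + 1], log10(hi))
        if (b > a) s <- s + ct[j] * (b - a) / (le[j + 1] - le[j])
      }
      s
    }
    expect_equal(sum(binCounts(al$h1)), overlapMass(h1), tolerance = 1e-9)
    expect_equal(sum(binCounts(al$h2)), overlapMass(h2), tolerance = 1e-9)
  }
})

test_that("histogram CSV round-trips bit-exactly and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  h <- fluorescenceHistogram(c(1, 10.123456789012345, 100, 1000),
                             c(5, 7, 9), threshold = 12.5,
                             label = "toy histogram")
  writeHistogram(h, path)
  back <- readHistogram(path)
  expect_identical(binEdges(back), binEdges(h))
  expect_identical(binCounts(back), binCounts(h))
  expect_identical(autofluorescenceThreshold(back),
                   autofluorescenceThreshold(h))
  expect_identical(histLabel(back), histLabel(h))

  # missing column
  writeLines(c("# threshold=1", "bin_lo,bin_hi,count", "1,10"), path)
  expect_error(readHistogram(path), "expected 3 columns")
  # negative count names the row
  writeLines(c("# threshold=1", "bin_lo,bin_hi,count", "1,10,5", "10,100,-2"),
             path)
  expect_error(readHistogram(path), "row 2.*negative count")
  # non-monotone edges
  writeLines(c("# threshold=1", "bin_lo,bin_hi,count", "10,10,5"), path)
  expect_error(readHistogram(path), "not strictly increasing")
  # non-contiguous bins
  writeLines(c("# threshold=1", "bin_lo,bin_hi,count", "1,10,5", "20,100,2"),
             path)
  expect_error(readHistogram(path), "not contiguous")
})
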