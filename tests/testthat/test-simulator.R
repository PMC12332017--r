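test_that("sampleFounders draws bins multinomially and respects bin ranges", {
  h <- fluorescenceHistogram(c(10, 100, 1000, 10000), c(2, 5, 3))
  expect_equal(nrow(sampleFounders(h, 0)), 0)
  # single-bin histogram: founders confined to the bin
  h1 <- fluorescenceHistogram(c(100, 1000), 4)
  set.seed(1)
  f <- sampleFounders(h1, 500)
  expect_true(all(f$fluorescence >= 100 & f$fluorescence <= 1000))
  expect_true(all(f$divisionsDone == 0L))
  # empirical frequencies within 3 multinomial standard errors
  set.seed(2)
  n <- 1e5
  f <- sampleFounders(h, n)
  bins <- findInterval(f$fluorescence, binEdges(h), rightmost.closed = TRUE)
  p <- binCounts(h) / sum(binCounts(h))
  for (j in 1:3) {
    se <- sqrt(p[j] * (1 - p[j]) / n)
    expect_lt(abs(mean(bins == j) - p[j]), 3 * se)
  }
  # all-zero histogram errors
  expect_error(sampleFounders(fluorescenceHistogram(c(1, 10), 0), 5),
               "no events")
})

test_that("sampleDivisionTime draws an exact truncated normal", {
  # near-degenerate sd stays glued to the mean
  law <- divisionLaw(50, 0.01, 21, 504)
  expect_true(all(abs(sampleDivisionTime(law, 1000) - 50) < 0.05))
  # point support is constant
  expect_equal(sampleDivisionTime(divisionLaw(50, 5, 50, 50), 10), rep(50, 10))
  # draws always within support even when the support clips hard
  lawEdge <- divisionLaw(21, 40, 21, 504)
  d <- sampleDivisionTime(lawEdge, 5000)
  expect_true(all(d >= 21 & d <= 504))
  # sample mean within 1% of the analytic truncated-normal mean
  law2 <- divisionLaw(44.94, 19.71, 21, 504)
  a <- (21 - 44.94) / 19.71; b <- (504 - 44.94) / 19.71
  analytic <- 44.94 + 19.71 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  set.seed(3)
  expect_equal(mean(sampleDivisionTime(law2, 1e5)), analytic,
               tolerance = 0.01)
})

test_that("deterministic synchronous lineages match the closed form", {
  # worked case: 1 founder at 1024 a.u., tau = 50 h, horizon 168 h
  cells <- simulatePopulation(1024, divisionLaw(50, 0.01, 50, 50), 168,
                              threshold = 1, synchronous = TRUE)
  expect_equal(nrow(cells), 8)
  expect_true(all(cells$fluorescence == 128))
  expect_true(all(cells$divisionsDone == 3L))
  # grid equivalence with analyticExpectedState, incl. the horizon boundary
  grid <- expand.grid(f0 = c(512, 1024, 3000), tau = c(50, 168, 504, 600),
                      horizon = c(168, 504))
  # the closed form has no division cap: stay within its domain (<= 8
  # doublings, the cap's own behaviour is tested separately)
  grid <- grid[floor(grid$horizon / grid$tau) <= 8, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    exp <- analyticExpectedState(g$f0, g$tau, g$horizon)
    cells <- simulatePopulation(g$f0, divisionLaw(g$tau, 0.01, g$tau, g$tau),
                                g$horizon, threshold = 0, synchronous = TRUE)
    expect_equal(nrow(cells), exp$cells)
    expect_true(all(cells$divisionsDone == exp$divisions))
    expect_true(all(cells$fluorescence == exp$fluorescence))
  }
  expect_equal(analyticExpectedState(512, 504, 504),
               list(divisions = 1L, cells = 2L, fluorescence = 256))
  expect_equal(analyticExpectedState(1000, 600, 504),
               list(divisions = 0L, cells = 1L, fluorescence = 1000))
})

test_that("lineages leave tracking below the threshold and at the division cap", {
  # 1000 a.u. founder with threshold 10: daughters of the 7th division fall
  # to 7.8125 a.u. and the lineage disappears
  fast <- divisionLaw(21, 0.01, 21, 21)
  cells <- simulatePopulation(1000, fast, 504, threshold = 10,
                              synchronous = TRUE)
  expect_equal(nrow(cells), 0)
  expect_equal(attr(cells, "droppedLineages"), 2^7)
  maxDiv <- simulatePopulation(1000, fast, 504, threshold = 10,
                               synchronous = TRUE, maxDivisions = 6)
  expect_true(all(maxDiv$divisionsDone == 6L))
  expect_equal(nrow(maxDiv), 2^6)
  # threshold 0: the cap bounds the population at 2^maxDivisions per founder
  capped <- simulatePopulation(1000, fast, 504, threshold = 0,
                               synchronous = TRUE)
  expect_equal(nrow(capped), 2^8)
  expect_true(all(capped$divisionsDone == 8L))
})

test_that("division halves fluorescence exactly, conserving lineage total", {
  set.seed(5)
  law <- divisionLaw(45, 15, 21, 504)
  cells <- simulatePopulation(rep(1000, 50), law, 168, threshold = 0)
  # every cell's fluorescence is 1000 / 2^divisions
  expect_true(all(cells$fluorescence == 1000 / 2^cells$divisionsDone))
  # total lineage fluorescence invariant: each division splits f into two
  # exact halves, so with threshold 0 the cohort total stays founders * f0
  expect_equal(sum(cells$fluorescence), 50 * 1000)
})

test_that("simulateDilution is seed-reproducible and threshold-monotone", {
  init <- generateInitialHistogram(3000, seed = 9)
  m2 <- decodeParameters(c(0.31, 44.94, 19.71), standardModels()[["2"]])
  h1 <- simulateDilution(m2, init, simulationConfig(168, 1500, seed = 4))
  h2 <- simulateDilution(m2, init, simulationConfig(168, 1500, seed = 4))
  expect_identical(binCounts(h1), binCounts(h2))
  expect_identical(binEdges(h1), binEdges(h2))
  # raising the threshold never increases the events retained
  init2 <- fluorescenceHistogram(binEdges(init), binCounts(init), 300)
  h3 <- simulateDilution(m2, init2, simulationConfig(168, 1500, seed = 4))
  expect_lte(sum(binCounts(h3)), sum(binCounts(h1)))
})

test_that("an all-quiescent model reproduces its input distribution", {
  init <- generateInitialHistogram(10000, seed = 10)
  # quiescent proportion 1 (proliferating proportion = remainder 0)
  m2 <- decodeParameters(c(1, 45, 15), standardModels()[["2"]])
  out <- simulateDilution(m2, init, simulationConfig(504, 10000, seed = 11))
  al <- alignBins(truncateAtThreshold(init), out)
  expect_lt(hellinger(al$h1, al$h2, "probability"), 0.05)
})

test_that("simulateDilution rejects invalid input", {
  init <- generateInitialHistogram(500, seed = 1)
  m2 <- decodeParameters(c(0.3, 45, 15), standardModels()[["2"]])
  expect_error(simulationConfig(-1, 10), "horizon")
  expect_error(simulateDilution(standardModels()[["2"]], init,
                                simulationConfig(168, 10)),
               "template")
})
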