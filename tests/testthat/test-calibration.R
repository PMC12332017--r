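test_that("fitness is zero on self-comparison and non-negative generally", {
  exp <- smallExperiment(seed = 21, nAcquire = 2000, founders = 2000)
  init <- experimentInitial(exp)
  tgt <- experimentTargets(exp)
  m2 <- standardModels()[["2"]]
  st <- reducedSettings(foundersPerEval = 500L)
  # a target equal to the simulated histogram scores 0 in both modes
  pm <- decodeParameters(c(0.3, 45, 15), m2)
  sim <- suppressWarnings(simulateDilution(pm, truncateAtThreshold(init),
                                           simulationConfig(168, 500, seed = 3)))
  expect_equal(hellinger(sim, sim, "count"), 0)
  expect_equal(hellinger(sim, sim, "probability"), 0)
  # generic non-negativity on random vectors
  set.seed(31)
  b <- searchBounds(m2)
  for (i in 1:5) {
    v <- runif(3, b[, "lo"], b[, "hi"])
    f <- fitnessOf(v, m2, init, tgt, st)
    expect_gte(f, 0)
  }
  # infeasible remainder scores +Inf
  m3 <- standardModels()[["3"]]
  expect_equal(fitnessOf(c(0.8, 0.8, 30, 100, 5, 10), m3, init, tgt, st), Inf)
  # an all-quiescent vector against a target equal to the initial histogram
  # differs only by sampling noise
  stProb <- calibrationSettings(hellingerMode = "probability",
                                foundersPerEval = 10000L, seed = 1)
  set.seed(41)
  fq <- fitnessOf(c(1, 45, 15), m2, init, list("168" = init), stProb)
  expect_lt(fq, 0.05)
})

test_that("fitness requires horizon metadata on the targets", {
  exp <- smallExperiment(seed = 22, nAcquire = 1000, founders = 1000)
  m2 <- standardModels()[["2"]]
  st <- reducedSettings(foundersPerEval = 200L)
  tgt <- experimentTargets(exp)
  expect_error(fitnessOf(c(0.3, 45, 15), m2, experimentInitial(exp),
                         unname(tgt), st), "horizon")
  expect_error(fitnessOf(c(0.3, 45, 15), m2, experimentInitial(exp),
                         tgt[[1]], st), "named list")
})

test_that("psoOptimize solves the sphere and honors bounds", {
  sphere <- function(x) sum(x^2)
  res <- psoOptimize(sphere, rep(-5, 3), rep(5, 3), swarmSize = 50,
                     iterations = 100, seed = 1)
  expect_lt(res$value, 1e-2)
  expect_length(res$trace, 100)
  expect_true(all(diff(res$trace) <= 1e-12))
  expect_equal(res$value, res$trace[100])
  # iterations = 1 returns the best of the initial swarm
  set.seed(2)
  init <- psoOptimize(sphere, rep(-5, 2), rep(5, 2), swarmSize = 30,
                      iterations = 1, seed = 2)
  expect_length(init$trace, 1)
  # every evaluated position stays within bounds (objective spies on calls)
  seen <- list()
  spy <- function(x) { seen[[length(seen) + 1L]] <<- x; sum(x^2) }
  psoOptimize(spy, c(-1, 0), c(2, 3), swarmSize = 10, iterations = 20,
              seed = 3)
  pos <- do.call(rbind, seen)
  expect_true(all(pos[, 1] >= -1 & pos[, 1] <= 2))
  expect_true(all(pos[, 2] >= 0 & pos[, 2] <= 3))
  # degenerate bound freezes the dimension
  frozen <- psoOptimize(spy, c(-1, 1.5), c(2, 1.5), swarmSize = 5,
                        iterations = 5, seed = 4)
  expect_equal(frozen$par[2], 1.5)
})

test_that("calibrate is deterministic and never leaves the search bounds", {
  exp <- smallExperiment(seed = 23, nAcquire = 1500, founders = 1500)
  m2 <- standardModels()[["2"]]
  st <- reducedSettings(seed = 5, swarmSize = 8L, iterations = 6L,
                        repetitions = 2L, foundersPerEval = 300L)
  r1 <- calibrate(m2, experimentInitial(exp), experimentTargets(exp), st)
  r2 <- calibrate(m2, experimentInitial(exp), experimentTargets(exp), st)
  expect_identical(bestVector(r1), bestVector(r2))
  expect_identical(bestFitness(r1), bestFitness(r2))
  expect_identical(fitnessTrace(r1), fitnessTrace(r2))
  # result invariants
  rb <- repetitionBests(r1)
  expect_equal(nrow(rb), 2)
  expect_equal(bestFitness(r1), min(rb$fitness))
  expect_true(all(diff(fitnessTrace(r1)) <= 1e-12))
  expect_equal(bestFitness(r1), tail(fitnessTrace(r1), 1))
  b <- searchBounds(m2)
  for (j in seq_len(nrow(b))) {
    expect_true(all(rb[[rownames(b)[j]]] >= b[j, "lo"]))
    expect_true(all(rb[[rownames(b)[j]]] <= b[j, "hi"]))
  }
  # a single repetition is its own best
  st1 <- reducedSettings(seed = 6, swarmSize = 6L, iterations = 4L,
                         repetitions = 1L, foundersPerEval = 200L)
  r3 <- calibrate(m2, experimentInitial(exp), experimentTargets(exp), st1)
  expect_equal(nrow(repetitionBests(r3)), 1)
  expect_equal(repetitionBests(r3)$fitness, bestFitness(r3))
  # empty targets are rejected
  expect_error(calibrate(m2, experimentInitial(exp), list(), st1),
               "at least one target")
})
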