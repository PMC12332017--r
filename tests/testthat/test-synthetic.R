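test_that("generateInitialHistogram places the requested mass above threshold", {
  h <- generateInitialHistogram(10000, log10Mean = 4, log10Sd = 0.2,
                                threshold = 100, seed = 1)
  expect_equal(sum(binCounts(h)), 10000)
  # reproducible under the same seed
  h2 <- generateInitialHistogram(10000, log10Mean = 4, log10Sd = 0.2,
                                 threshold = 100, seed = 1)
  expect_identical(binCounts(h2), binCounts(h))
  # >= 99% of mass above threshold (3-sigma rule on the log axis)
  tr <- truncateAtThreshold(h)
  expect_gte(sum(binCounts(tr)) / sum(binCounts(h)), 0.99)
  # brightness invariant enforced
  expect_error(generateInitialHistogram(100, log10Mean = 2, log10Sd = 0.5,
                                        threshold = 100),
               "not clearly above threshold")
})

test_that("ground truths decode and validate under the models module", {
  expect_error(groundTruthSpec(2, c(0.3, 45, 15), log10Mean = 2,
                               log10Sd = 0.5, threshold = 100),
               "not clearly above")
  for (gt in list(defaultGroundTruth(),
                  groundTruthSpec(4, c(0.5, 40, 150, 8, 30), seed = 2),
                  groundTruthSpec(1, c(45, 15), seed = 3))) {
    m <- decodeParameters(gt@vector,
                          standardModels()[[as.character(modelId(gt))]])
    expect_length(validateModel(m), 0)
  }
})

test_that("generateExperiment subsamples to the acquisition count and dilutes over time", {
  exp <- generateExperiment(defaultGroundTruth(seed = 7), nAcquire = 3000,
                            founders = 3000)
  expect_named(experimentTargets(exp), c("168", "504"))
  for (t in experimentTargets(exp))
    expect_equal(sum(binCounts(t)), 3000)
  # all histograms share binning and threshold
  init <- experimentInitial(exp)
  for (t in experimentTargets(exp)) {
    expect_identical(binEdges(t)[1], binEdges(init)[1])
    expect_identical(autofluorescenceThreshold(t),
                     autofluorescenceThreshold(init))
  }
  # determinism: same truth, byte-identical experiment
  exp2 <- generateExperiment(defaultGroundTruth(seed = 7), nAcquire = 3000,
                             founders = 3000)
  expect_identical(binCounts(experimentTargets(exp2)[["504"]]),
                   binCounts(experimentTargets(exp)[["504"]]))
  # an all-quiescent truth reproduces the initial distribution at any horizon
  truthQ <- groundTruthSpec(2, c(1, 45, 15), seed = 8)
  expQ <- generateExperiment(truthQ, horizons = 504, nAcquire = 10000,
                             founders = 10000)
  al <- alignBins(truncateAtThreshold(experimentInitial(expQ)),
                  experimentTargets(expQ)[["504"]])
  expect_lt(hellinger(al$h1, al$h2, "probability"), 0.05)
})

test_that("label dilution is monotone in the chase horizon", {
  # fraction of simulated cells (before acquisition subsampling) still above
  # threshold shrinks with the horizon for any proliferating truth
  truth <- defaultGroundTruth(seed = 9)
  model <- decodeParameters(truth@vector, standardModels()[["2"]])
  set.seed(truth@seed)
  init <- generateInitialHistogram(5000, truth@log10Mean, truth@log10Sd,
                                   threshold = truth@threshold)
  fr <- vapply(c(168, 504), function(hr) {
    sim <- suppressWarnings(simulateDilution(model, init,
      simulationConfig(hr, 5000, seed = 10)))
    sum(binCounts(sim)) / 5000
  }, numeric(1))
  expect_lt(fr[2], fr[1])
})

test_that("fixtures round-trip bit-exactly with a checksum manifest", {
  exp <- generateExperiment(defaultGroundTruth(seed = 11), nAcquire = 500,
                            founders = 500)
  dir <- withr::local_tempdir()
  manifest <- writeFixture(exp, dir)
  expect_true(file.exists(file.path(dir, "initial.csv")))
  expect_true(file.exists(file.path(dir, "target_168.csv")))
  expect_true(file.exists(file.path(dir, "target_504.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_setequal(man$files$name,
                  c("initial.csv", "target_168.csv", "target_504.csv",
                    "ground_truth.json"))
  # checksums match the files on disk
  expect_identical(unname(tools::md5sum(file.path(dir, man$files$name))),
                   man$files$md5)
  back <- readFixture(dir)
  expect_identical(binCounts(experimentInitial(back)),
                   binCounts(experimentInitial(exp)))
  expect_identical(binEdges(experimentInitial(back)),
                   binEdges(experimentInitial(exp)))
  for (hr in c("168", "504"))
    expect_identical(binCounts(experimentTargets(back)[[hr]]),
                     binCounts(experimentTargets(exp)[[hr]]))
  expect_equal(groundTruth(back)@vector, groundTruth(exp)@vector)
  # missing directory errors with the path
  expect_error(writeFixture(exp, file.path(dir, "nope")), "nope")
})
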