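# Shared fixtures: tiny histograms and reduced-size experiments built in code.

toyHistogram <- function(counts = c(5, 7, 9), edges = c(1, 10, 100, 1000),
                         threshold = 0) {
  fluorescenceHistogram(edges, counts, threshold)
}

# random small histogram on fixed edges, positive total
randomHistogram <- function(nBins = 6L, edges = 10^seq(0, 3, length.out = nBins + 1)) {
  counts <- stats::rpois(nBins, lambda = 4)
  if (sum(counts) == 0) counts[1L] <- 1
  fluorescenceHistogram(edges, counts)
}

# small synthetic experiment for pipeline tests
smallExperiment <- function(vector = c(0.30, 45, 15), modelId = 2L, seed = 1L,
                            horizons = 168, nAcquire = 4000L,
                            founders = 4000L) {
  truth <- groundTruthSpec(modelId, vector, seed = seed)
  generateExperiment(truth, horizons = horizons, nAcquire = nAcquire,
                     founders = founders)
}

reducedSettings <- function(seed = 1L, swarmSize = 20L, iterations = 30L,
                            repetitions = 3L, foundersPerEval = 1000L) {
  calibrationSettings(swarmSize = swarmSize, iterations = iterations,
                      repetitions = repetitions,
                      foundersPerEval = foundersPerEval, seed = seed)
}
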