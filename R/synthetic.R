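#' @include AllClasses.R simulator.R calibration.R
NULL

#' Construct the ground truth of a synthetic label-retention experiment
#'
#' @param modelId generating model structure (1--4, see [standardModels()]).
#' @param vector true free-parameter vector in optimizer encoding (see
#'   [decodeParameters()]).
#' @param log10Mean,log10Sd log10-scale mean and sd of founder fluorescence;
#'   the initial population must sit clearly above the threshold
#'   (\code{log10Mean - 3*log10Sd > log10(threshold)}).
#' @param threshold autofluorescence threshold (a.u.).
#' @param seed integer seed.
#' @return a validated [GroundTruth-class]; the vector is checked to decode
#'   under the chosen standard model.
#' @export
groundTruthSpec <- function(modelId, vector, log10Mean = 4, log10Sd = 0.2,
                            threshold = 100, seed = 1L) {
  gt <- new("GroundTruth", modelId = as.integer(modelId),
            vector = as.numeric(vector), log10Mean = as.numeric(log10Mean),
            log10Sd = as.numeric(log10Sd), threshold = as.numeric(threshold),
            seed = as.integer(seed))
  decodeParameters(gt@vector, standardModels()[[as.character(gt@modelId)]])
  gt
}

#' Reference ground truth of the quiescent + proliferating structure
#'
#' Model 2 parameterized at the package's reference estimates for melanoma
#' label retention: 31\% quiescent cells and a proliferating population
#' dividing every 44.94 +/- 19.71 h (truncated to 21--504 h), with a bright
#' log-normal initial population (log10 mean 4, sd 0.2) over a threshold of
#' 100 a.u. The canonical regression fixture of the package.
#'
#' @param seed integer seed (default 1).
#' @return a [GroundTruth-class].
#' @export
defaultGroundTruth <- function(seed = 1L) {
  groundTruthSpec(2L, c(0.31, 44.94, 19.71), log10Mean = 4, log10Sd = 0.2,
                  threshold = 100, seed = seed)
}

#' Generate a pre-chase fluorescence histogram
#'
#' Draws \code{nEvents} fluorescence values log-normally (base-10 normal on
#' the log axis), emulating the unimodal reporter-expression peak of an
#' uninduced (no-chase) sample, and bins them. Draws outside the binning
#' range are redrawn so the histogram holds exactly \code{nEvents} events.
#'
#' @param nEvents number of events (>= 1).
#' @param log10Mean,log10Sd log10-scale mean and sd of fluorescence.
#' @param spec a [BinSpec-class] (default: 256 log bins over \[1, 1e5\]).
#' @param threshold autofluorescence threshold; \code{log10Mean - 3*log10Sd}
#'   must exceed \code{log10(threshold)} so the population is clearly bright.
#' @param seed optional integer seed (\code{NA} = ambient RNG stream).
#' @return a [FluorescenceHistogram-class] with \code{sum(binCounts()) ==
#'   nEvents}.
#' @export
generateInitialHistogram <- function(nEvents, log10Mean = 4, log10Sd = 0.2,
                                     spec = binSpec(), threshold = 100,
                                     seed = NA_integer_) {
  nEvents <- as.integer(nEvents)
  stopifnot(nEvents >= 1L)
  thrLog <- if (threshold > 0) log10(threshold) else -Inf
  if (!(log10Mean - 3 * log10Sd > thrLog))
    stop("initial population not clearly above threshold: need ",
         "log10Mean - 3*log10Sd > log10(threshold)", call. = FALSE)
  if (!is.na(seed)) set.seed(as.integer(seed))
  draws <- 10^stats::rnorm(nEvents, log10Mean, log10Sd)
  lo <- spec@lo; hi <- spec@hi
  bad <- which(draws < lo | draws > hi)
  guard <- 0L
  while (length(bad)) {
    draws[bad] <- 10^stats::rnorm(length(bad), log10Mean, log10Sd)
    bad <- which(draws < lo | draws > hi)
    guard <- guard + 1L
    if (guard > 1000L)
      stop("cannot place events within the binning range", call. = FALSE)
  }
  h <- buildHistogram(draws, spec, threshold, label = "synthetic initial")
  h
}

#' Generate a complete synthetic label-retention experiment
#'
#' Builds the pre-chase histogram from the ground truth's founder-intensity
#' law, simulates forward dilution under the true model to each horizon, and
#' multinomially subsamples every simulated histogram to exactly
#' \code{nAcquire} events, emulating fixed-event-count cytometer acquisition
#' (histogram noise is thereby decoupled from simulated population size).
#'
#' @param truth a [GroundTruth-class] (e.g. [defaultGroundTruth()]).
#' @param horizons chase horizons in hours; default \code{c(168, 504)} (1 and
#'   3 weeks).
#' @param nAcquire events acquired per target histogram.
#' @param founders simulated founder cells per horizon.
#' @param spec binning ([BinSpec-class]); shared by all histograms.
#' @return a [SyntheticExperiment-class].
#' @examples
#' exp <- generateExperiment(defaultGroundTruth(seed = 7), nAcquire = 2000,
#'                           founders = 2000)
#' experimentTargets(exp)[["168"]]
#' @export
generateExperiment <- function(truth, horizons = c(168, 504),
                               nAcquire = 10000L, founders = 10000L,
                               spec = binSpec()) {
  stopifnot(is(truth, "GroundTruth"))
  validObject(truth)
  stopifnot(length(horizons) >= 1L, all(horizons > 0))
  nAcquire <- as.integer(nAcquire); founders <- as.integer(founders)
  model <- decodeParameters(truth@vector,
                            standardModels()[[as.character(truth@modelId)]])
  set.seed(truth@seed)
  initial <- generateInitialHistogram(nAcquire, truth@log10Mean,
                                      truth@log10Sd, spec, truth@threshold)
  targets <- vector("list", length(horizons))
  names(targets) <- as.character(horizons)
  for (i in seq_along(horizons)) {
    sim <- suppressWarnings(simulateDilution(model, initial,
      simulationConfig(horizons[i], founders)))
    tot <- sum(sim@counts)
    if (!length(sim@counts) || tot <= 0)
      stop("simulated histogram at ", horizons[i], " h holds no events above ",
           "the threshold; lower the threshold or shorten the horizon",
           call. = FALSE)
    sub <- as.numeric(stats::rmultinom(1L, nAcquire, prob = sim@counts))
    ## re-expand the truncated simulation output onto the full shared binning
    ## (zero counts below the truncation point) so every histogram of the
    ## experiment lives on identical edges
    counts <- numeric(length(initial@counts))
    offset <- length(initial@counts) - length(sim@counts)
    counts[offset + seq_along(sub)] <- sub
    targets[[i]] <- fluorescenceHistogram(initial@binEdges, counts,
      sim@threshold,
      label = sprintf("synthetic target at %g h (%d acquired events)",
                      horizons[i], nAcquire))
  }
  new("SyntheticExperiment", initial = initial, targets = targets,
      groundTruth = truth, acquisitionEvents = nAcquire)
}

#' Write / read a synthetic experiment as a plain-text fixture
#'
#' \code{writeFixture} writes \code{initial.csv}, one
#' \code{target_<hours>.csv} per horizon, \code{ground_truth.json} and a
#' \code{manifest.json} listing every written file with its MD5 checksum.
#' \code{readFixture} reconstructs the experiment; the round trip is
#' bit-exact.
#'
#' @param exp a [SyntheticExperiment-class].
#' @param directory an existing writable directory.
#' @return \code{writeFixture} returns the manifest path invisibly;
#'   \code{readFixture} returns the [SyntheticExperiment-class].
#' @export
writeFixture <- function(exp, directory) {
  stopifnot(is(exp, "SyntheticExperiment"))
  if (!dir.exists(directory))
    stop("no such directory: ", directory, call. = FALSE)
  files <- character(0)
  f <- file.path(directory, "initial.csv")
  writeHistogram(exp@initial, f); files <- c(files, f)
  for (hr in names(exp@targets)) {
    f <- file.path(directory, sprintf("target_%s.csv", hr))
    writeHistogram(exp@targets[[hr]], f); files <- c(files, f)
  }
  gt <- exp@groundTruth
  f <- file.path(directory, "ground_truth.json")
  jsonlite::write_json(list(
    model_id = gt@modelId, vector = gt@vector, log10_mean = gt@log10Mean,
    log10_sd = gt@log10Sd, threshold = gt@threshold, seed = gt@seed,
    acquisition_events = exp@acquisitionEvents,
    horizons = as.numeric(names(exp@targets))),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  manifest <- file.path(directory, "manifest.json")
  jsonlite::write_json(list(files = data.frame(
    name = basename(files), md5 = unname(tools::md5sum(files)))),
    manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' @rdname writeFixture
#' @export
readFixture <- function(directory) {
  gtPath <- file.path(directory, "ground_truth.json")
  if (!file.exists(gtPath))
    stop("no ground_truth.json in ", directory, call. = FALSE)
  doc <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
  truth <- groundTruthSpec(doc$model_id, doc$vector, doc$log10_mean,
                           doc$log10_sd, doc$threshold, doc$seed)
  initial <- readHistogram(file.path(directory, "initial.csv"))
  targets <- list()
  for (hr in as.character(doc$horizons))
    targets[[hr]] <- readHistogram(file.path(directory,
                                             sprintf("target_%s.csv", hr)))
  new("SyntheticExperiment", initial = initial, targets = targets,
      groundTruth = truth,
      acquisitionEvents = as.integer(doc$acquisition_events))
}
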