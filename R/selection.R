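#' @include AllClasses.R calibration.R
NULL

#' Five-number summary with linear-interpolation quantiles
#'
#' Summarizes replicate fitness values with the linear-interpolation quantile
#' convention (the one where the 25\% quantile of \code{1:5} is 2), so the
#' summary is deterministic across platforms.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector: \code{min}, \code{q25}, \code{median},
#'   \code{q75}, \code{max}.
#' @examples
#' summarizeFitness(1:5)
#' @export
summarizeFitness <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values))
    stop("values must be a non-empty numeric vector without NA", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(min = min(values), q25 = q[1L], median = q[2L], q75 = q[3L],
    max = max(values))
}

#' Validate a calibrated model by replicate simulation
#'
#' Re-simulates the calibrated model \code{nRuns} times per chase horizon and
#' scores each run against the corresponding target histogram with the
#' calibration fitness, yielding one fitness distribution per horizon (the
#' machine twin of a violin-plot panel). This captures the spread introduced
#' purely by the stochastic initialization and division schedule.
#'
#' @param model a [ProliferationModel-class] template.
#' @param bestVector calibrated free-parameter vector.
#' @param initial pre-chase [FluorescenceHistogram-class].
#' @param targets named list of target histograms (names = horizon hours);
#'   typically the 168 h calibration window plus a 504 h validation window.
#' @param nRuns simulations per horizon (default 100).
#' @param settings a [CalibrationSettings-class] (founders and Hellinger mode
#'   are reused).
#' @param seed integer seed for the replicate simulations.
#' @return list of [FitnessDistribution-class], one per target horizon, named
#'   like \code{targets}.
#' @export
validateModelFit <- function(model, bestVector, initial, targets, nRuns = 100L,
                             settings = calibrationSettings(), seed = 1L) {
  stopifnot(is(model, "ProliferationModel"),
            is(settings, "CalibrationSettings"))
  targets <- .normalizeTargets(targets)
  initial <- truncateAtThreshold(initial)
  pm <- decodeParameters(bestVector, model)
  nRuns <- as.integer(nRuns)
  stopifnot(nRuns >= 1L)
  set.seed(as.integer(seed))
  hrs <- as.numeric(names(targets))
  out <- vector("list", length(targets))
  names(out) <- names(targets)
  for (i in seq_along(targets)) {
    vals <- numeric(nRuns)
    for (r in seq_len(nRuns)) {
      sim <- suppressWarnings(simulateDilution(pm, initial,
        simulationConfig(hrs[i], settings@foundersPerEval)))
      vals[r] <- .histFitness(sim, targets[[i]], settings@hellingerMode)
    }
    out[[i]] <- new("FitnessDistribution", modelId = model@modelId,
                    horizon = hrs[i], values = vals,
                    stats = summarizeFitness(vals))
  }
  out
}

## Core ranking on named medians. Models whose median lies within
## `tolerance` of the best median (relatively) form a tie band re-ordered by
## ascending free-parameter count; everything else ranks by median.
.rankMedians <- function(medians, paramCounts, tolerance) {
  ids <- names(medians)
  if (is.null(ids) || is.null(names(paramCounts)))
    stop("medians and paramCounts must be named by model id", call. = FALSE)
  if (!all(ids %in% names(paramCounts)))
    stop("paramCounts missing entries for some models", call. = FALSE)
  if (length(medians) < 2L)
    stop("ranking needs at least two models", call. = FALSE)
  pc <- paramCounts[ids]
  ## deterministic pure-median order (ties by parameter count, then id)
  ordMedian <- order(medians, pc, ids)
  best <- min(medians)
  inBand <- medians <= best * (1 + tolerance)
  key <- ifelse(inBand, 0, 1)
  ord <- order(key, ifelse(inBand, pc, 0), medians, ids)
  ranking <- data.frame(modelId = as.integer(ids[ord]),
                        median = as.numeric(medians[ord]),
                        paramCount = as.integer(pc[ord]),
                        rank = seq_along(ord))
  rationale <- if (ord[1L] == ordMedian[1L]) "fitness-dominant" else
    "parsimony-tiebreak"
  new("SelectionReport", ranking = ranking,
      chosenModelId = ranking$modelId[1L], rationale = rationale,
      tolerance = as.numeric(tolerance), distributions = list())
}

#' @describeIn rankModels rank from a named numeric vector of median
#'   validation fitnesses (names = model ids).
#' @export
setMethod("rankModels", signature(distributions = "numeric"),
  function(distributions, paramCounts, tolerance = 0.05) {
    .rankMedians(distributions, paramCounts, tolerance)
  })

#' @describeIn rankModels rank from a list of [FitnessDistribution-class]
#'   objects, one per model, all at the ranking horizon.
#' @export
setMethod("rankModels", signature(distributions = "list"),
  function(distributions, paramCounts, tolerance = 0.05) {
    stopifnot(all(vapply(distributions, is, logical(1),
                         "FitnessDistribution")))
    meds <- vapply(distributions, function(d) d@stats[["median"]], numeric(1))
    names(meds) <- vapply(distributions, function(d) as.character(d@modelId),
                          character(1))
    rep <- .rankMedians(meds, paramCounts, tolerance)
    rep@distributions <- distributions
    validObject(rep)
    rep
  })

#' Compare candidate models end to end on one experiment
#'
#' Convenience pipeline: calibrates each candidate model against the
#' calibration target(s), validates every calibrated model at all supplied
#' horizons with \code{nRuns} replicate simulations, and ranks the models by
#' median validation fitness at the ranking horizon with the parsimony
#' tie-break.
#'
#' @param models list of [ProliferationModel-class] templates (e.g. a subset
#'   of [standardModels()]).
#' @param initial pre-chase histogram.
#' @param targets named list of target histograms (names = horizon hours).
#' @param calibrationTargets names of \code{targets} used during calibration
#'   (default: the shortest horizon, mirroring calibration at the 1-week
#'   window with later validation).
#' @param rankingHorizon name of the horizon used for ranking (default: the
#'   longest horizon).
#' @param nRuns validation simulations per model and horizon.
#' @param tolerance relative median tolerance of the tie band.
#' @param settings a [CalibrationSettings-class].
#' @return a [SelectionReport-class] whose \code{distributions} slot holds all
#'   per-model, per-horizon [FitnessDistribution-class] objects; calibration
#'   results are attached as attribute \code{"calibrations"} of the report's
#'   ranking data.frame.
#' @export
selectModel <- function(models, initial, targets,
                        calibrationTargets = NULL, rankingHorizon = NULL,
                        nRuns = 100L, tolerance = 0.05,
                        settings = calibrationSettings()) {
  targets <- .normalizeTargets(targets)
  hrs <- as.numeric(names(targets))
  if (is.null(calibrationTargets))
    calibrationTargets <- names(targets)[which.min(hrs)]
  if (is.null(rankingHorizon))
    rankingHorizon <- names(targets)[which.max(hrs)]
  stopifnot(all(calibrationTargets %in% names(targets)),
            rankingHorizon %in% names(targets))
  calibs <- vector("list", length(models))
  allDists <- list()
  rankDists <- vector("list", length(models))
  pcs <- numeric(length(models))
  ids <- character(length(models))
  seeds <- .repSeeds(settings@seed + 7L, length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    ids[i] <- as.character(m@modelId)
    pcs[i] <- freeParameterCount(m)
    calibs[[i]] <- calibrate(m, initial, targets[calibrationTargets], settings)
    dists <- validateModelFit(m, calibs[[i]]@bestVector, initial, targets,
                              nRuns = nRuns, settings = settings,
                              seed = seeds[i])
    allDists <- c(allDists, dists)
    rankDists[[i]] <- dists[[rankingHorizon]]
  }
  names(pcs) <- ids
  report <- rankModels(rankDists, pcs, tolerance)
  report@distributions <- allDists
  attr(report@ranking, "calibrations") <- calibs
  report
}
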