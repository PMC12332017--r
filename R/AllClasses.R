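#' @import methods
NULL

## ---------------------------------------------------------------------------
## Histogram containers
## ---------------------------------------------------------------------------

#' FluorescenceHistogram: binned flow-cytometry fluorescence events
#'
#' Container for a single-channel fluorescence histogram as acquired on a
#' cytometer: strictly increasing positive bin edges (so a log-scale axis is
#' meaningful), non-negative per-bin event counts, and the experimentally
#' determined autofluorescence threshold below which labelled cells cannot be
#' distinguished from background. The empty histogram (zero bins) is a valid
#' degenerate state produced e.g. by truncating above all recorded signal.
#'
#' @slot binEdges numeric, length B+1 (or length 0 for the empty histogram);
#'   strictly increasing, all positive; arbitrary fluorescence units.
#' @slot counts numeric, length B; finite and non-negative.
#' @slot threshold single non-negative numeric; autofluorescence threshold in
#'   the same units as \code{binEdges}.
#' @slot label free-text provenance tag.
#'
#' @seealso [buildHistogram()], [truncateAtThreshold()], [hellinger()]
#' @export
setClass("FluorescenceHistogram",
  representation(
    binEdges  = "numeric",
    counts    = "numeric",
    threshold = "numeric",
    label     = "character"
  ),
  prototype(binEdges = numeric(0), counts = numeric(0),
            threshold = 0, label = "")
)

setValidity("FluorescenceHistogram", function(object) {
  msg <- character(0)
  e <- object@binEdges
  ct <- object@counts
  if (length(ct) == 0L) {
    if (length(e) != 0L)
      msg <- c(msg, "empty histogram must have zero-length binEdges")
  } else {
    if (length(e) != length(ct) + 1L)
      msg <- c(msg, "length(binEdges) must equal length(counts) + 1")
    if (anyNA(e) || any(!is.finite(e)))
      msg <- c(msg, "binEdges must be finite")
    else {
      if (any(e <= 0)) msg <- c(msg, "binEdges must all be > 0")
      if (any(diff(e) <= 0)) msg <- c(msg, "binEdges must be strictly increasing")
    }
    if (anyNA(ct) || any(!is.finite(ct)))
      msg <- c(msg, "counts must be finite")
    else if (any(ct < 0))
      msg <- c(msg, "counts must be >= 0")
  }
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0)
    msg <- c(msg, "threshold must be a single value >= 0")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' BinSpec: histogram binning specification
#'
#' Describes the fluorescence axis of a histogram to be built from raw
#' per-event values. The default (see [binSpec()]) is 256 log10-spaced bins
#' spanning 1 to 1e5 a.u., mimicking a 5-decade cytometer axis.
#'
#' @slot lo,hi lowest/highest bin edge (a.u.), \code{lo < hi}; \code{lo > 0}
#'   when \code{scale == "log10"}.
#' @slot nBins positive integer number of bins.
#' @slot scale \code{"log10"} or \code{"linear"} bin spacing.
#' @export
setClass("BinSpec",
  representation(lo = "numeric", hi = "numeric", nBins = "integer",
                 scale = "character"))

setValidity("BinSpec", function(object) {
  msg <- character(0)
  if (length(object@lo) != 1L || length(object@hi) != 1L ||
      !is.finite(object@lo) || !is.finite(object@hi) || object@lo >= object@hi)
    msg <- c(msg, "need finite lo < hi")
  if (length(object@nBins) != 1L || is.na(object@nBins) || object@nBins < 1L)
    msg <- c(msg, "nBins must be >= 1")
  if (!identical(object@scale, "log10") && !identical(object@scale, "linear"))
    msg <- c(msg, "scale must be 'log10' or 'linear'")
  else if (identical(object@scale, "log10") &&
           length(object@lo) == 1L && !is.na(object@lo) && object@lo <= 0)
    msg <- c(msg, "log10 scale requires lo > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Proliferation models
## ---------------------------------------------------------------------------

#' DivisionLaw: truncated-normal cell-cycle time distribution
#'
#' Division intervals are drawn from a normal distribution with the given mean
#' and standard deviation, truncated to \code{[supportLo, supportHi]} hours.
#' The support doubles as the biologically admissible range of division times
#' for the subpopulation (e.g. 21--504 h for a generic proliferating
#' population).
#'
#' @slot mean,sd mean and standard deviation of the untruncated normal, hours.
#' @slot supportLo,supportHi truncation bounds, hours; \code{supportLo > 0}
#'   and \code{supportLo <= mean <= supportHi}.
#' @export
setClass("DivisionLaw",
  representation(mean = "numeric", sd = "numeric",
                 supportLo = "numeric", supportHi = "numeric"))

setValidity("DivisionLaw", function(object) {
  msg <- character(0)
  v <- c(object@mean, object@sd, object@supportLo, object@supportHi)
  if (length(v) != 4L)
    return("mean, sd, supportLo, supportHi must be single values")
  if (anyNA(c(object@supportLo, object@supportHi)) ||
      any(!is.finite(c(object@supportLo, object@supportHi))))
    return("supportLo and supportHi must be finite")
  if (object@supportLo <= 0) msg <- c(msg, "supportLo must be > 0")
  if (object@supportLo > object@supportHi)
    msg <- c(msg, "supportLo must be <= supportHi")
  ## NA mean/sd mark an unparameterized template law
  if (!is.na(object@mean) &&
      (object@mean < object@supportLo || object@mean > object@supportHi))
    msg <- c(msg, "mean must lie within [supportLo, supportHi]")
  if (!is.na(object@sd) && object@sd < 0) msg <- c(msg, "sd must be >= 0")
  if (length(msg)) msg else TRUE
})

setClassUnion("DivisionLawOrNULL", c("DivisionLaw", "NULL"))

#' Subpopulation: one kinetic compartment of a proliferation model
#'
#' A named fraction of the cell population sharing one division-time law.
#' Quiescent subpopulations carry no law (\code{law = NULL}): they do not
#' divide within any simulation horizon. In an unparameterized model template
#' the proportion (and the law's mean/sd) are \code{NA} until [decodeParameters()]
#' fills them from an optimizer vector.
#'
#' @slot name one of \code{"quiescent"}, \code{"proliferating"},
#'   \code{"fast"}, \code{"slow"}.
#' @slot proportion fraction of the population in [0, 1], or \code{NA} in a
#'   template.
#' @slot law a [DivisionLaw-class] or \code{NULL} for quiescence.
#' @export
setClass("Subpopulation",
  representation(name = "character", proportion = "numeric",
                 law = "DivisionLawOrNULL"))

setValidity("Subpopulation", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L ||
      !object@name %in% c("quiescent", "proliferating", "fast", "slow"))
    msg <- c(msg, "name must be quiescent/proliferating/fast/slow")
  if (length(object@proportion) != 1L)
    msg <- c(msg, "proportion must be a single value")
  else if (!is.na(object@proportion) &&
           (object@proportion < 0 || object@proportion > 1))
    msg <- c(msg, "proportion must lie in [0, 1]")
  if (identical(object@name, "quiescent") && !is.null(object@law))
    msg <- c(msg, "quiescent subpopulations carry no division law")
  if (length(msg)) msg else TRUE
})

#' ProliferationModel: a candidate subpopulation structure
#'
#' One of the four standard label-retention model structures (see
#' [standardModels()]), or a fully parameterized instance thereof. The
#' \code{bounds} slot stores the box search space of the free parameter vector
#' (free proportions first, then means, then standard deviations, in
#' subpopulation order) used by the optimizer.
#'
#' @slot modelId integer model identifier (1--4 for the standard menu).
#' @slot subpopulations ordered list of [Subpopulation-class] objects.
#' @slot bounds numeric matrix with columns \code{lo}, \code{hi} and one row
#'   per free parameter; row names name the parameters.
#' @export
setClass("ProliferationModel",
  representation(modelId = "integer", subpopulations = "list",
                 bounds = "matrix"))

setValidity("ProliferationModel", function(object) {
  msg <- character(0)
  if (length(object@modelId) != 1L || is.na(object@modelId))
    msg <- c(msg, "modelId must be a single integer")
  if (!length(object@subpopulations))
    msg <- c(msg, "at least one subpopulation required")
  if (!all(vapply(object@subpopulations, is, logical(1), "Subpopulation")))
    msg <- c(msg, "subpopulations must all be Subpopulation objects")
  b <- object@bounds
  if (!is.numeric(b) || ncol(b) != 2L)
    msg <- c(msg, "bounds must be a numeric matrix with columns lo, hi")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulation & calibration containers
## ---------------------------------------------------------------------------

#' SimulationConfig: settings of one forward dilution simulation
#'
#' @slot horizon chase duration in hours (> 0).
#' @slot founders number of simulated founder cells sampled from the initial
#'   histogram (>= 1).
#' @slot maxDivisions division-tracking cap; after this many divisions a
#'   cell's signal is treated as background and it never divides again
#'   (default 8).
#' @slot synchronousStart if \code{TRUE}, every proliferating founder's first
#'   division occurs exactly one full division interval after time zero
#'   (deterministic test mode); the default \code{FALSE} draws a uniform phase
#'   so founders divide asynchronously.
#' @slot seed integer RNG seed, or \code{NA} to use the ambient RNG stream.
#' @export
setClass("SimulationConfig",
  representation(horizon = "numeric", founders = "integer",
                 maxDivisions = "integer", synchronousStart = "logical",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@horizon) != 1L || is.na(object@horizon) ||
      object@horizon <= 0)
    msg <- c(msg, "horizon must be a single value > 0")
  if (length(object@founders) != 1L || is.na(object@founders) ||
      object@founders < 1L)
    msg <- c(msg, "founders must be >= 1")
  if (length(object@maxDivisions) != 1L || is.na(object@maxDivisions) ||
      object@maxDivisions < 1L)
    msg <- c(msg, "maxDivisions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CalibrationSettings: particle-swarm calibration configuration
#'
#' Defaults mirror the reference analysis: 50 particles, 100 iterations and
#' 30 independent repetitions per model, with the raw-count Hellinger mode.
#'
#' @slot swarmSize number of PSO particles.
#' @slot iterations PSO iterations (the first evaluates the initial swarm).
#' @slot repetitions independent seeded optimization repetitions.
#' @slot foundersPerEval founder cells per fitness simulation.
#' @slot hellingerMode \code{"count"} or \code{"probability"}.
#' @slot simsPerEval simulations averaged per fitness evaluation.
#' @slot seed master seed from which repetition seeds are derived.
#' @export
setClass("CalibrationSettings",
  representation(swarmSize = "integer", iterations = "integer",
                 repetitions = "integer", foundersPerEval = "integer",
                 hellingerMode = "character", simsPerEval = "integer",
                 seed = "integer"))

setValidity("CalibrationSettings", function(object) {
  msg <- character(0)
  ints <- c(swarmSize = object@swarmSize, iterations = object@iterations,
            repetitions = object@repetitions,
            foundersPerEval = object@foundersPerEval,
            simsPerEval = object@simsPerEval)
  bad <- names(ints)[is.na(ints) | ints < 1L]
  if (length(bad)) msg <- c(msg, paste(paste(bad, collapse = ", "),
                                       "must be positive"))
  if (!object@hellingerMode %in% c("count", "probability"))
    msg <- c(msg, "hellingerMode must be 'count' or 'probability'")
  if (length(msg)) msg else TRUE
})

#' CalibrationResult: outcome of a repeated swarm calibration
#'
#' @slot modelId identifier of the calibrated model.
#' @slot bestVector best free-parameter vector found across repetitions.
#' @slot bestFitness its fitness (the minimum over repetition bests).
#' @slot repetitionVectors matrix of per-repetition best vectors (one row per
#'   repetition).
#' @slot repetitionFitness per-repetition best fitness values.
#' @slot trace non-increasing best-so-far fitness curve of the winning
#'   repetition, one entry per iteration.
#' @export
setClass("CalibrationResult",
  representation(modelId = "integer", bestVector = "numeric",
                 bestFitness = "numeric", repetitionVectors = "matrix",
                 repetitionFitness = "numeric", trace = "numeric"))

setValidity("CalibrationResult", function(object) {
  msg <- character(0)
  if (length(object@repetitionFitness) &&
      abs(object@bestFitness - min(object@repetitionFitness)) > 1e-12 &&
      is.finite(object@bestFitness))
    msg <- c(msg, "bestFitness must equal the minimum repetition fitness")
  if (length(object@trace) > 1L && any(diff(object@trace) > 1e-12))
    msg <- c(msg, "trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Validation & selection containers
## ---------------------------------------------------------------------------

#' FitnessDistribution: replicate validation fitnesses for one model/horizon
#'
#' The machine twin of a violin-plot panel: the raw fitness values from
#' repeated simulation of one calibrated model at one chase horizon, plus the
#' five-number summary computed with linear-interpolation quantiles.
#'
#' @slot modelId model identifier.
#' @slot horizon chase horizon in hours.
#' @slot values non-negative fitness values, one per validation run.
#' @slot stats named numeric: \code{min}, \code{q25}, \code{median},
#'   \code{q75}, \code{max}.
#' @export
setClass("FitnessDistribution",
  representation(modelId = "integer", horizon = "numeric",
                 values = "numeric", stats = "numeric"))

setValidity("FitnessDistribution", function(object) {
  msg <- character(0)
  if (!length(object@values)) msg <- c(msg, "values must be non-empty")
  else if (any(object@values < 0)) msg <- c(msg, "fitness values must be >= 0")
  need <- c("min", "q25", "median", "q75", "max")
  if (!all(need %in% names(object@stats)))
    msg <- c(msg, "stats must contain min, q25, median, q75, max")
  else {
    s <- object@stats[need]
    if (any(diff(s) < -1e-12)) msg <- c(msg, "stats must be ordered")
  }
  if (length(msg)) msg else TRUE
})

#' SelectionReport: ranked model comparison with parsimony tie-break
#'
#' @slot ranking data.frame with columns \code{modelId}, \code{median},
#'   \code{paramCount} and \code{rank}, ordered by rank.
#' @slot chosenModelId the rank-1 model.
#' @slot rationale \code{"fitness-dominant"} if the lowest-median model was
#'   chosen outright, \code{"parsimony-tiebreak"} if a simpler model within
#'   the tolerance band displaced it.
#' @slot tolerance relative median tolerance defining the tie band.
#' @slot distributions optional list of [FitnessDistribution-class] objects
#'   underlying the ranking (possibly at several horizons).
#' @export
setClass("SelectionReport",
  representation(ranking = "data.frame", chosenModelId = "integer",
                 rationale = "character", tolerance = "numeric",
                 distributions = "list"))

setValidity("SelectionReport", function(object) {
  msg <- character(0)
  if (!nrow(object@ranking)) msg <- c(msg, "ranking must be non-empty")
  else if (object@ranking$modelId[1L] != object@chosenModelId)
    msg <- c(msg, "chosen model must be ranked first")
  if (!object@rationale %in% c("fitness-dominant", "parsimony-tiebreak"))
    msg <- c(msg, "rationale must be fitness-dominant or parsimony-tiebreak")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic experiments
## ---------------------------------------------------------------------------

#' GroundTruth: known generating parameters of a synthetic experiment
#'
#' @slot modelId generating model structure (1--4, see [standardModels()]).
#' @slot vector true free-parameter vector in optimizer encoding.
#' @slot log10Mean,log10Sd log10-scale mean and sd of founder fluorescence
#'   (the pre-chase reporter-expression law).
#' @slot threshold autofluorescence threshold (a.u.). The initial population
#'   must be clearly label-bright: \code{log10Mean - 3*log10Sd >
#'   log10(threshold)}.
#' @slot seed integer seed making the experiment reproducible.
#' @export
setClass("GroundTruth",
  representation(modelId = "integer", vector = "numeric",
                 log10Mean = "numeric", log10Sd = "numeric",
                 threshold = "numeric", seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (object@log10Sd <= 0) msg <- c(msg, "log10Sd must be > 0")
  if (object@threshold < 0) msg <- c(msg, "threshold must be >= 0")
  thr <- if (object@threshold > 0) log10(object@threshold) else -Inf
  if (!(object@log10Mean - 3 * object@log10Sd > thr))
    msg <- c(msg,
      "initial population not clearly above threshold (need log10Mean - 3*log10Sd > log10(threshold))")
  if (length(msg)) msg else TRUE
})

#' SyntheticExperiment: a complete simulated label-retention experiment
#'
#' @slot initial pre-chase [FluorescenceHistogram-class].
#' @slot targets named list of post-chase histograms; names are chase horizons
#'   in hours.
#' @slot groundTruth the [GroundTruth-class] that generated the data.
#' @slot acquisitionEvents events acquired per target histogram (each target's
#'   total count equals this).
#' @export
setClass("SyntheticExperiment",
  representation(initial = "FluorescenceHistogram", targets = "list",
                 groundTruth = "GroundTruth", acquisitionEvents = "integer"))

setValidity("SyntheticExperiment", function(object) {
  msg <- character(0)
  if (!length(object@targets) || is.null(names(object@targets)))
    msg <- c(msg, "targets must be a non-empty named list (names = hours)")
  else {
    if (!all(vapply(object@targets, is, logical(1), "FluorescenceHistogram")))
      msg <- c(msg, "targets must be FluorescenceHistogram objects")
    tot <- vapply(object@targets, function(h) sum(h@counts), numeric(1))
    if (any(abs(tot - object@acquisitionEvents) > 1e-9))
      msg <- c(msg, "each target's total counts must equal acquisitionEvents")
  }
  if (length(msg)) msg else TRUE
})
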