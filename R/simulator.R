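#' @include AllClasses.R models.R histograms.R
NULL

#' Construct simulation settings
#'
#' @param horizon chase duration in hours.
#' @param founders number of founder cells to sample from the initial
#'   histogram.
#' @param maxDivisions division-tracking cap (default 8): after this many
#'   divisions the reporter signal is treated as indistinguishable from
#'   autofluorescence and the cell never divides again.
#' @param synchronousStart deterministic test mode: first divisions occur
#'   exactly one full division interval after time zero instead of at a
#'   uniform random phase.
#' @param seed integer seed, or \code{NA} (default) to draw from the ambient
#'   RNG stream.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(horizon, founders, maxDivisions = 8L,
                             synchronousStart = FALSE, seed = NA_integer_) {
  new("SimulationConfig", horizon = as.numeric(horizon),
      founders = as.integer(founders), maxDivisions = as.integer(maxDivisions),
      synchronousStart = isTRUE(synchronousStart), seed = as.integer(seed))
}

#' Construct a division-time law
#'
#' @param mean,sd mean and sd (hours) of the underlying normal distribution.
#' @param supportLo,supportHi truncation bounds (hours).
#' @return a [DivisionLaw-class].
#' @export
divisionLaw <- function(mean, sd, supportLo, supportHi) {
  new("DivisionLaw", mean = as.numeric(mean), sd = as.numeric(sd),
      supportLo = as.numeric(supportLo), supportHi = as.numeric(supportHi))
}

## Truncated-normal sampling by inversion of the truncated CDF (exact even
## when the support sits far from the mean, unlike naive rejection).
.rtruncnormLaw <- function(n, law) {
  if (n == 0L) return(numeric(0))
  lo <- law@supportLo; hi <- law@supportHi
  if (hi <= lo) return(rep(lo, n))
  if (law@sd <= 0) return(rep(min(max(law@mean, lo), hi), n))
  a <- stats::pnorm(lo, law@mean, law@sd)
  b <- stats::pnorm(hi, law@mean, law@sd)
  x <- stats::qnorm(a + stats::runif(n) * (b - a), law@mean, law@sd)
  pmin(pmax(x, lo), hi)
}

#' Draw division times from a truncated-normal law
#'
#' @param law a [DivisionLaw-class].
#' @param n number of draws.
#' @return numeric vector of division intervals (hours), always within the
#'   law's support.
#' @export
sampleDivisionTime <- function(law, n = 1L) {
  stopifnot(is(law, "DivisionLaw"))
  validObject(law)
  if (is.na(law@mean) || is.na(law@sd))
    stop("division law is an unparameterized template", call. = FALSE)
  .rtruncnormLaw(as.integer(n), law)
}

#' Sample founder cells from an initial histogram
#'
#' Founder bins are drawn multinomially proportionally to the histogram
#' counts; within the chosen bin the fluorescence is drawn log-uniformly.
#'
#' @param initial a [FluorescenceHistogram-class] with positive total counts.
#' @param n number of founders.
#' @return data.frame with columns \code{fluorescence} (a.u.) and
#'   \code{divisionsDone} (all 0).
#' @export
sampleFounders <- function(initial, n) {
  stopifnot(is(initial, "FluorescenceHistogram"))
  validObject(initial)
  n <- as.integer(n)
  if (n == 0L)
    return(data.frame(fluorescence = numeric(0), divisionsDone = integer(0)))
  tot <- sum(initial@counts)
  if (!length(initial@counts) || tot <= 0)
    stop("initial histogram has no events to sample founders from",
         call. = FALSE)
  bins <- sample.int(length(initial@counts), n, replace = TRUE,
                     prob = initial@counts)
  llo <- log10(initial@binEdges[bins])
  lhi <- log10(initial@binEdges[bins + 1L])
  data.frame(fluorescence = 10^stats::runif(n, llo, lhi),
             divisionsDone = rep(0L, n))
}

## Core branching engine. `fluor` are founder fluorescences, `lawIdx` maps
## each founder to an entry of `laws` (NULL entries = quiescent). Cells whose
## fluorescence falls below `threshold` after a division leave the tracked
## population together with their descendants; cells reaching `maxDivisions`
## stay but never divide again. Division events at t <= horizon execute.
.simulateEngine <- function(fluor, lawIdx, laws, horizon, threshold,
                            maxDivisions, synchronous) {
  n <- length(fluor)
  divs <- rep(0L, n)
  tnext <- rep(Inf, n)
  for (j in seq_along(laws)) {
    if (is.null(laws[[j]])) next
    idx <- which(lawIdx == j)
    if (!length(idx)) next
    tau <- .rtruncnormLaw(length(idx), laws[[j]])
    tnext[idx] <- if (synchronous) tau else stats::runif(length(idx)) * tau
  }
  droppedLineages <- 0L
  keep0 <- fluor >= threshold
  droppedLineages <- droppedLineages + sum(!keep0)
  fluor <- fluor[keep0]; divs <- divs[keep0]
  tnext <- tnext[keep0]; lawIdx <- lawIdx[keep0]

  repeat {
    act <- which(tnext <= horizon)
    if (!length(act)) break
    fD <- rep(fluor[act] / 2, 2L)
    dD <- rep(divs[act] + 1L, 2L)
    lD <- rep(lawIdx[act], 2L)
    tD <- rep(tnext[act], 2L)
    tau <- numeric(length(fD))
    for (j in unique(lD)) {
      jj <- which(lD == j)
      tau[jj] <- .rtruncnormLaw(length(jj), laws[[j]])
    }
    tD <- tD + tau
    tD[dD >= maxDivisions] <- Inf
    keepD <- fD >= threshold
    droppedLineages <- droppedLineages + sum(!keepD)
    fluor <- c(fluor[-act], fD[keepD])
    divs <- c(divs[-act], dD[keepD])
    tnext <- c(tnext[-act], tD[keepD])
    lawIdx <- c(lawIdx[-act], lD[keepD])
  }
  list(fluorescence = fluor, divisionsDone = divs, lawIdx = lawIdx,
       droppedLineages = droppedLineages)
}

#' Simulate a single-law founder cohort (low-level engine access)
#'
#' Runs the branching engine on explicitly given founder fluorescences, all
#' governed by one division law (or none). Mainly useful for analytic checks
#' and custom workflows; [simulateDilution()] is the histogram-level
#' interface.
#'
#' @param fluorescence numeric vector of founder fluorescences (a.u.).
#' @param law a [DivisionLaw-class], or \code{NULL} for a quiescent cohort.
#' @param horizon chase duration (hours).
#' @param threshold autofluorescence threshold; lineages dropping below it are
#'   no longer tracked.
#' @param maxDivisions division cap (default 8).
#' @param synchronous if \code{TRUE}, first divisions occur exactly one full
#'   interval after time zero.
#' @return data.frame of tracked cells alive at the horizon with columns
#'   \code{fluorescence} and \code{divisionsDone}; attribute
#'   \code{"droppedLineages"} counts lineages lost below the threshold.
#' @export
simulatePopulation <- function(fluorescence, law, horizon, threshold = 0,
                               maxDivisions = 8L, synchronous = FALSE) {
  if (!is.null(law)) {
    stopifnot(is(law, "DivisionLaw"))
    validObject(law)
  }
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  st <- .simulateEngine(as.numeric(fluorescence),
                        rep(1L, length(fluorescence)), list(law),
                        horizon, threshold, as.integer(maxDivisions),
                        isTRUE(synchronous))
  out <- data.frame(fluorescence = st$fluorescence,
                    divisionsDone = st$divisionsDone)
  attr(out, "droppedLineages") <- st$droppedLineages
  out
}

#' Simulate label dilution from an initial histogram
#'
#' Samples founder cells from the initial histogram, assigns each to a model
#' subpopulation multinomially by the model proportions, and simulates
#' asynchronous division with per-division fluorescence halving up to the
#' horizon. Proliferating founders schedule their first division at
#' \code{u * tau} with \code{u ~ U(0, 1)} and \code{tau} a fresh
#' truncated-normal draw (uniform phase within the first cycle); with
#' \code{synchronousStart = TRUE} the first division occurs at \code{tau}
#' exactly. At each division a cell is replaced by two daughters with half its
#' fluorescence and independently redrawn division intervals. A lineage stops
#' being tracked when its fluorescence falls below the autofluorescence
#' threshold (descendants can only be dimmer) or after \code{maxDivisions}
#' divisions, past which the cell persists but no longer divides.
#'
#' @param model a fully parameterized [ProliferationModel-class] (see
#'   [decodeParameters()]).
#' @param initial pre-chase [FluorescenceHistogram-class]; its binning and
#'   autofluorescence threshold are used for the output.
#' @param config a [SimulationConfig-class].
#' @return a [FluorescenceHistogram-class] of tracked cells alive at the
#'   horizon, truncated at the threshold (see [truncateAtThreshold()]); the
#'   label records founders and dropped-lineage counts.
#' @examples
#' m2 <- decodeParameters(c(0.31, 44.94, 19.71), standardModels()[["2"]])
#' init <- generateInitialHistogram(2000, log10Mean = 4, log10Sd = 0.2,
#'                                  threshold = 100, seed = 1)
#' simulateDilution(m2, init, simulationConfig(168, 2000, seed = 1))
#' @export
simulateDilution <- function(model, initial, config) {
  stopifnot(is(model, "ProliferationModel"),
            is(initial, "FluorescenceHistogram"),
            is(config, "SimulationConfig"))
  validObject(config)
  v <- validateModel(model)
  if (length(v)) stop("invalid model: ", paste(v, collapse = "; "),
                      call. = FALSE)
  props <- vapply(model@subpopulations, function(s) s@proportion, numeric(1))
  if (anyNA(props))
    stop("model is an unparameterized template; decodeParameters() first",
         call. = FALSE)
  if (!is.na(config@seed)) set.seed(config@seed)

  founders <- sampleFounders(initial, config@founders)
  k <- length(model@subpopulations)
  assign <- if (k == 1L) rep(1L, nrow(founders)) else
    sample.int(k, nrow(founders), replace = TRUE, prob = props)
  laws <- lapply(model@subpopulations, function(s) s@law)
  st <- .simulateEngine(founders$fluorescence, assign, laws,
                        config@horizon, initial@threshold,
                        config@maxDivisions, config@synchronousStart)

  edges <- initial@binEdges
  idx <- findInterval(st$fluorescence, edges, rightmost.closed = TRUE)
  inRange <- idx >= 1L & idx <= length(initial@counts)
  counts <- tabulate(idx[inRange], nbins = length(initial@counts))
  h <- fluorescenceHistogram(edges, counts, initial@threshold,
    label = sprintf(
      "simulated: model %d, horizon %g h, %d founders, %d lineages dropped below threshold, %d cells out of binning range",
      model@modelId, config@horizon, config@founders, st$droppedLineages,
      sum(!inRange)))
  out <- suppressWarnings(truncateAtThreshold(h))
  if (!length(out@counts) || sum(out@counts) == 0)
    warning("no tracked cells above the autofluorescence threshold at the horizon",
            call. = FALSE)
  out
}

#' Closed-form state of a deterministic, synchronous lineage
#'
#' For a constant division interval \code{tau} and synchronous start, a
#' founder of fluorescence \code{f0} has undergone \code{k =
#' floor(horizon / tau)} doublings by the horizon (division events at
#' \code{t <= horizon} count, so a division exactly at the horizon executes),
#' leaving \code{2^k} cells at \code{f0 / 2^k} a.u. each. Used as the
#' analytic oracle for the stochastic engine in its deterministic limit.
#'
#' @param f0 founder fluorescence (a.u.).
#' @param tau division interval (hours, > 0).
#' @param horizon chase duration (hours).
#' @return list with elements \code{divisions}, \code{cells},
#'   \code{fluorescence}.
#' @examples
#' analyticExpectedState(1024, 50, 168)  # 3 divisions, 8 cells at 128 a.u.
#' @export
analyticExpectedState <- function(f0, tau, horizon) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  k <- floor(horizon / tau + 1e-12)
  list(divisions = as.integer(k), cells = as.integer(2^k),
       fluorescence = f0 / 2^k)
}
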