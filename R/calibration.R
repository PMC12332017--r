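#' @include AllClasses.R models.R simulator.R
NULL

#' Construct calibration settings
#'
#' Defaults follow the reference protocol: 50 particles, 100 iterations,
#' 30 repetitions, raw-count Hellinger fitness, one simulation per
#' evaluation.
#'
#' @param swarmSize,iterations,repetitions PSO shape (see
#'   [CalibrationSettings-class]).
#' @param foundersPerEval founder cells per fitness simulation (default 1000).
#' @param hellingerMode \code{"count"} (default) or \code{"probability"}.
#' @param simsPerEval simulations averaged per fitness evaluation.
#' @param seed master seed; repetition seeds are derived from it.
#' @return a [CalibrationSettings-class].
#' @export
calibrationSettings <- function(swarmSize = 50L, iterations = 100L,
                                repetitions = 30L, foundersPerEval = 1000L,
                                hellingerMode = c("count", "probability"),
                                simsPerEval = 1L, seed = 1L) {
  hellingerMode <- match.arg(hellingerMode)
  new("CalibrationSettings", swarmSize = as.integer(swarmSize),
      iterations = as.integer(iterations), repetitions = as.integer(repetitions),
      foundersPerEval = as.integer(foundersPerEval),
      hellingerMode = hellingerMode, simsPerEval = as.integer(simsPerEval),
      seed = as.integer(seed))
}

## Normalize a `targets` argument into a named list of truncated histograms;
## names are chase horizons in hours.
.normalizeTargets <- function(targets) {
  if (is(targets, "FluorescenceHistogram"))
    stop("targets must be a named list; names give the chase horizon in hours",
         call. = FALSE)
  if (!length(targets)) stop("at least one target histogram is required",
                             call. = FALSE)
  hrs <- suppressWarnings(as.numeric(names(targets)))
  if (is.null(names(targets)) || anyNA(hrs) || any(hrs <= 0))
    stop("target list names must be positive chase horizons in hours",
         call. = FALSE)
  lapply(targets, function(h) {
    stopifnot(is(h, "FluorescenceHistogram"))
    truncateAtThreshold(h)
  })
}

## Hellinger fitness of one simulated histogram against one truncated target.
## In count mode the simulated counts are first rescaled so their total over
## the shared truncated support equals the target's total: the fitness then
## measures distribution shape rather than population growth.
.histFitness <- function(sim, target, mode) {
  if (!length(sim@counts))
    sim <- fluorescenceHistogram(target@binEdges, rep(0, length(target@counts)),
                                 target@threshold)
  if (!.sameBinning(sim@binEdges, target@binEdges)) {
    al <- alignBins(sim, target)
    sim <- al$h1; target <- al$h2
  }
  if (mode == "count") {
    simTot <- sum(sim@counts)
    tgtTot <- sum(target@counts)
    cs <- if (simTot > 0) sim@counts * (tgtTot / simTot) else sim@counts
    sqrt(sum((sqrt(cs) - sqrt(target@counts))^2))
  } else {
    hellinger(sim, target, mode = "probability")
  }
}

#' Fitness of a free-parameter vector against target histograms
#'
#' Decodes the vector, simulates the parameterized model from the initial
#' histogram to each target's horizon, and returns the summed (over targets)
#' mean (over \code{simsPerEval}) Hellinger distance between simulated and
#' target histograms, both truncated at the autofluorescence threshold. In
#' count mode simulated counts are rescaled to the target's total over the
#' shared truncated support before comparison. Vectors with a negative
#' remainder proportion are infeasible and score \code{+Inf}.
#'
#' @param vector numeric free-parameter vector (see [decodeParameters()]).
#' @param model a [ProliferationModel-class] template.
#' @param initial pre-chase [FluorescenceHistogram-class].
#' @param targets named list of target histograms; names are chase horizons in
#'   hours (e.g. \code{list("168" = h)}).
#' @param settings a [CalibrationSettings-class].
#' @return single non-negative fitness (lower is better), possibly \code{Inf}.
#' @export
fitnessOf <- function(vector, model, initial, targets, settings) {
  stopifnot(is(settings, "CalibrationSettings"))
  targets <- .normalizeTargets(targets)
  pm <- tryCatch(decodeParameters(vector, model),
                 flowDilution_infeasible = function(e) NULL)
  if (is.null(pm)) return(Inf)
  hrs <- as.numeric(names(targets))
  total <- 0
  for (i in seq_along(targets)) {
    acc <- 0
    for (s in seq_len(settings@simsPerEval)) {
      sim <- suppressWarnings(simulateDilution(pm, initial,
        simulationConfig(hrs[i], settings@foundersPerEval)))
      acc <- acc + .histFitness(sim, targets[[i]], settings@hellingerMode)
    }
    total <- total + acc / settings@simsPerEval
  }
  total
}

#' Bound-constrained global-best particle swarm optimization
#'
#' A standard constricted global-best PSO: positions are initialized uniformly
#' within the bounds with zero velocities; velocities are updated with inertia
#' \code{w = 0.7298} and cognitive = social coefficient \code{1.49618}, and
#' clamped per dimension to half the bound width; positions leaving the box
#' are reflected onto the boundary with the offending velocity component
#' negated. The first iteration evaluates the initial swarm, so
#' \code{iterations = 1} returns the best initial particle. Because the
#' objective may be stochastic, the attraction point is re-evaluated once per
#' iteration to limit lock-in on lucky noise, while the returned optimum is
#' the best raw evaluation ever seen.
#'
#' @param objective function taking a numeric vector, returning a scalar to
#'   minimize (may return \code{Inf}).
#' @param lower,upper numeric bound vectors (finite, \code{lower <= upper};
#'   a dimension with \code{lower == upper} is frozen at that value).
#' @param swarmSize,iterations swarm shape; defaults 50 and 100.
#' @param seed optional integer seed; \code{NULL} uses the ambient RNG stream.
#' @return list with \code{par} (best position), \code{value} (its objective
#'   value) and \code{trace} (non-increasing best-so-far curve, length
#'   \code{iterations}).
#' @examples
#' sphere <- function(x) sum(x^2)
#' psoOptimize(sphere, rep(-5, 3), rep(5, 3), swarmSize = 20,
#'             iterations = 25, seed = 1)$value
#' @export
psoOptimize <- function(objective, lower, upper, swarmSize = 50L,
                        iterations = 100L, seed = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(lower)
  stopifnot(length(upper) == d, d >= 1L)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("bounds must be finite with lower <= upper", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  swarmSize <- as.integer(swarmSize); iterations <- as.integer(iterations)
  stopifnot(swarmSize >= 1L, iterations >= 1L)

  w <- 0.7298; c1 <- 1.49618; c2 <- 1.49618
  width <- upper - lower
  frozen <- width == 0
  vmax <- width / 2

  pos <- matrix(stats::runif(swarmSize * d, rep(lower, each = swarmSize),
                             rep(upper, each = swarmSize)),
                nrow = swarmSize)
  pos[, frozen] <- rep(lower[frozen], each = swarmSize)
  vel <- matrix(0, swarmSize, d)

  fit <- apply(pos, 1L, objective)
  pbestPos <- pos; pbestFit <- fit
  g <- which.min(fit)
  gbestPos <- pos[g, ]; gbestFit <- fit[g]
  bestEverPos <- gbestPos; bestEverFit <- gbestFit
  trace <- numeric(iterations)
  trace[1L] <- bestEverFit

  if (iterations > 1L) for (it in 2:iterations) {
    r1 <- matrix(stats::runif(swarmSize * d), swarmSize)
    r2 <- matrix(stats::runif(swarmSize * d), swarmSize)
    vel <- w * vel + c1 * r1 * (pbestPos - pos) +
      c2 * r2 * sweep(pos, 2L, gbestPos, function(x, g) g - x)
    vel <- pmin(pmax(vel, -rep(vmax, each = swarmSize)),
                rep(vmax, each = swarmSize))
    pos <- pos + vel
    ## reflect at the box boundary, negating the offending velocity component
    for (j in seq_len(d)) {
      if (frozen[j]) { pos[, j] <- lower[j]; vel[, j] <- 0; next }
      out <- pos[, j] < lower[j]
      if (any(out)) {
        pos[out, j] <- pmin(2 * lower[j] - pos[out, j], upper[j])
        vel[out, j] <- -vel[out, j]
      }
      out <- pos[, j] > upper[j]
      if (any(out)) {
        pos[out, j] <- pmax(2 * upper[j] - pos[out, j], lower[j])
        vel[out, j] <- -vel[out, j]
      }
    }
    fit <- apply(pos, 1L, objective)
    improved <- fit < pbestFit
    pbestPos[improved, ] <- pos[improved, , drop = FALSE]
    pbestFit[improved] <- fit[improved]
    if (min(fit) < bestEverFit) {
      g <- which.min(fit)
      bestEverPos <- pos[g, ]; bestEverFit <- fit[g]
    }
    ## refresh the attraction point against objective noise
    g <- which.min(pbestFit)
    gbestPos <- pbestPos[g, ]
    gbestFit <- objective(gbestPos)
    if (gbestFit < bestEverFit) {
      bestEverPos <- gbestPos; bestEverFit <- gbestFit
    }
    pbestFit[g] <- gbestFit
    trace[it] <- min(trace[it - 1L], bestEverFit)
  }
  list(par = bestEverPos, value = bestEverFit, trace = trace)
}

## Counter-based repetition seeds derived from the master seed: reproducible,
## independent of R's RNG state, and within 32-bit integer range.
.repSeeds <- function(master, n) {
  x <- (as.double(master) %% 2147483647) + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (x * 48271) %% 2147483647   # minstd step
    out[i] <- as.integer(x)
  }
  out
}

#' Calibrate a proliferation model against target histograms
#'
#' Runs \code{repetitions} independent particle-swarm optimizations of
#' [fitnessOf()] over the model's search bounds, each seeded from the master
#' seed, and returns the overall best parameterization together with every
#' repetition's best. With multiple targets the fitness is the sum over
#' targets.
#'
#' @param model a [ProliferationModel-class] template (see
#'   [standardModels()]).
#' @param initial pre-chase [FluorescenceHistogram-class].
#' @param targets named list of target histograms, names = horizon hours.
#' @param settings a [CalibrationSettings-class].
#' @return a [CalibrationResult-class].
#' @export
calibrate <- function(model, initial, targets, settings = calibrationSettings()) {
  stopifnot(is(model, "ProliferationModel"),
            is(settings, "CalibrationSettings"))
  targets <- .normalizeTargets(targets)
  initial <- truncateAtThreshold(initial)
  b <- model@bounds
  obj <- function(v) fitnessOf(v, model, initial, targets, settings)
  seeds <- .repSeeds(settings@seed, settings@repetitions)
  runs <- vector("list", settings@repetitions)
  for (r in seq_len(settings@repetitions)) {
    runs[[r]] <- psoOptimize(obj, b[, "lo"], b[, "hi"],
                             swarmSize = settings@swarmSize,
                             iterations = settings@iterations,
                             seed = seeds[r])
  }
  fits <- vapply(runs, `[[`, numeric(1), "value")
  vecs <- do.call(rbind, lapply(runs, `[[`, "par"))
  colnames(vecs) <- rownames(b)
  best <- which.min(fits)
  new("CalibrationResult", modelId = model@modelId,
      bestVector = runs[[best]]$par, bestFitness = fits[best],
      repetitionVectors = vecs, repetitionFitness = fits,
      trace = runs[[best]]$trace)
}
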