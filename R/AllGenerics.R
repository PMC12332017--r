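#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("autofluorescenceThreshold",
           function(x) standardGeneric("autofluorescenceThreshold"))
#' @rdname accessors
#' @export
setGeneric("histLabel", function(x) standardGeneric("histLabel"))
#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("subpopulations", function(x) standardGeneric("subpopulations"))
#' @rdname accessors
#' @export
setGeneric("searchBounds", function(x) standardGeneric("searchBounds"))
#' @rdname accessors
#' @export
setGeneric("bestVector", function(x) standardGeneric("bestVector"))
#' @rdname accessors
#' @export
setGeneric("bestFitness", function(x) standardGeneric("bestFitness"))
#' @rdname accessors
#' @export
setGeneric("fitnessTrace", function(x) standardGeneric("fitnessTrace"))
#' @rdname accessors
#' @export
setGeneric("repetitionBests", function(x) standardGeneric("repetitionBests"))
#' @rdname accessors
#' @export
setGeneric("fitnessValues", function(x) standardGeneric("fitnessValues"))
#' @rdname accessors
#' @export
setGeneric("fitnessStats", function(x) standardGeneric("fitnessStats"))
#' @rdname accessors
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))
#' @rdname accessors
#' @export
setGeneric("chosenModel", function(x) standardGeneric("chosenModel"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("experimentTargets", function(x) standardGeneric("experimentTargets"))
#' @rdname accessors
#' @export
setGeneric("experimentInitial", function(x) standardGeneric("experimentInitial"))

#' Rank candidate models by validation fitness with a parsimony tie-break
#'
#' @param distributions per-model validation fitness: either a list of
#'   [FitnessDistribution-class] objects (one per model, at the ranking
#'   horizon) or a named numeric vector of median fitnesses (names =
#'   model ids).
#' @param paramCounts named numeric vector of free-parameter counts, names
#'   matching the model ids.
#' @param tolerance relative tolerance on the median: all models whose median
#'   lies within \code{tolerance} of the best median (relative to the best)
#'   are treated as ties and re-ordered by ascending parameter count.
#'   Default 0.05.
#' @return a [SelectionReport-class].
#' @export
setGeneric("rankModels",
  function(distributions, paramCounts, tolerance = 0.05)
    standardGeneric("rankModels"))
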