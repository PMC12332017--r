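#' @include AllGenerics.R
NULL

#' Accessors for flowDilution classes
#'
#' Small accessor functions exposing the slots of the package's S4 containers;
#' user code should prefer these to direct \code{@} access.
#'
#' @param x an object of the appropriate class.
#' @return the corresponding slot value (see each class's documentation).
#' @name accessors
NULL

#' @rdname accessors
setMethod("binEdges", "FluorescenceHistogram", function(x) x@binEdges)
#' @rdname accessors
setMethod("binCounts", "FluorescenceHistogram", function(x) x@counts)
#' @rdname accessors
setMethod("autofluorescenceThreshold", "FluorescenceHistogram",
          function(x) x@threshold)
#' @rdname accessors
setMethod("histLabel", "FluorescenceHistogram", function(x) x@label)

#' @rdname accessors
setMethod("modelId", "ProliferationModel", function(x) x@modelId)
#' @rdname accessors
setMethod("modelId", "CalibrationResult", function(x) x@modelId)
#' @rdname accessors
setMethod("modelId", "FitnessDistribution", function(x) x@modelId)
#' @rdname accessors
setMethod("modelId", "GroundTruth", function(x) x@modelId)
#' @rdname accessors
setMethod("subpopulations", "ProliferationModel", function(x) x@subpopulations)
#' @rdname accessors
setMethod("searchBounds", "ProliferationModel", function(x) x@bounds)

#' @rdname accessors
setMethod("bestVector", "CalibrationResult", function(x) x@bestVector)
#' @rdname accessors
setMethod("bestFitness", "CalibrationResult", function(x) x@bestFitness)
#' @rdname accessors
setMethod("fitnessTrace", "CalibrationResult", function(x) x@trace)
#' @rdname accessors
setMethod("repetitionBests", "CalibrationResult", function(x) {
  data.frame(repetition = seq_along(x@repetitionFitness),
             fitness = x@repetitionFitness,
             x@repetitionVectors, check.names = FALSE)
})

#' @rdname accessors
setMethod("fitnessValues", "FitnessDistribution", function(x) x@values)
#' @rdname accessors
setMethod("fitnessStats", "FitnessDistribution", function(x) x@stats)

#' @rdname accessors
setMethod("ranking", "SelectionReport", function(x) x@ranking)
#' @rdname accessors
setMethod("chosenModel", "SelectionReport", function(x) x@chosenModelId)

#' @rdname accessors
setMethod("groundTruth", "SyntheticExperiment", function(x) x@groundTruth)
#' @rdname accessors
setMethod("experimentTargets", "SyntheticExperiment", function(x) x@targets)
#' @rdname accessors
setMethod("experimentInitial", "SyntheticExperiment", function(x) x@initial)

## show methods -------------------------------------------------------------

setMethod("show", "FluorescenceHistogram", function(object) {
  nb <- length(object@counts)
  cat("FluorescenceHistogram with", nb, "bins\n")
  if (nb) {
    cat(sprintf("  range: [%.4g, %.4g] a.u., total events: %.6g\n",
                object@binEdges[1L], object@binEdges[nb + 1L],
                sum(object@counts)))
  }
  cat(sprintf("  autofluorescence threshold: %.4g a.u.\n", object@threshold))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "DivisionLaw", function(object) {
  cat(sprintf(
    "DivisionLaw: normal(mean = %.4g h, sd = %.4g h) truncated to [%.4g, %.4g] h\n",
    object@mean, object@sd, object@supportLo, object@supportHi))
})

setMethod("show", "ProliferationModel", function(object) {
  cat(sprintf("ProliferationModel %d with %d subpopulation(s)\n",
              object@modelId, length(object@subpopulations)))
  for (sp in object@subpopulations) {
    pr <- if (is.na(sp@proportion)) "free" else sprintf("%.3f", sp@proportion)
    if (is.null(sp@law)) {
      cat(sprintf("  %-13s proportion %s, no division within horizon\n",
                  sp@name, pr))
    } else if (is.na(sp@law@mean)) {
      cat(sprintf("  %-13s proportion %s, division time free in [%g, %g] h\n",
                  sp@name, pr, sp@law@supportLo, sp@law@supportHi))
    } else {
      cat(sprintf("  %-13s proportion %s, division %.4g +/- %.4g h in [%g, %g]\n",
                  sp@name, pr, sp@law@mean, sp@law@sd,
                  sp@law@supportLo, sp@law@supportHi))
    }
  }
  cat(sprintf("  free parameters: %d\n", nrow(object@bounds)))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult for model %d\n", object@modelId))
  cat(sprintf("  best fitness %.6g over %d repetition(s)\n",
              object@bestFitness, length(object@repetitionFitness)))
  cat("  best vector:", paste(signif(object@bestVector, 6), collapse = ", "),
      "\n")
})

setMethod("show", "FitnessDistribution", function(object) {
  s <- object@stats
  cat(sprintf(
    "FitnessDistribution: model %d at %g h (%d runs)\n  min %.6f, 25%%: %.6f, median %.6f, 75%%: %.6f, max %.6f\n",
    object@modelId, object@horizon, length(object@values),
    s[["min"]], s[["q25"]], s[["median"]], s[["q75"]], s[["max"]]))
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: model %d selected (%s, tolerance %.3g)\n",
              object@chosenModelId, object@rationale, object@tolerance))
  print(object@ranking, row.names = FALSE)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: model %d, vector [%s]\n  founder law: log10 fluorescence ~ N(%.3g, %.3g); threshold %.4g a.u.; seed %d\n",
    object@modelId, paste(signif(object@vector, 6), collapse = ", "),
    object@log10Mean, object@log10Sd, object@threshold, object@seed))
})

setMethod("show", "SyntheticExperiment", function(object) {
  cat(sprintf(
    "SyntheticExperiment: model %d truth, horizons %s h, %d events/target\n",
    object@groundTruth@modelId, paste(names(object@targets), collapse = ", "),
    object@acquisitionEvents))
})
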