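#' @include AllClasses.R
NULL

## Search-space boundaries of the four standard structures: division-time
## mean ranges per subpopulation kind, with sd ranges in brackets.
.LAW_RANGES <- list(
  proliferating = list(mean = c(21, 504), sd = c(0.01, 40)),
  fast          = list(mean = c(21, 63),  sd = c(0.01, 30)),
  slow          = list(mean = c(63, 504), sd = c(0.01, 40))
)

.newSubpop <- function(name, proportion = NA_real_, law = NULL) {
  new("Subpopulation", name = name, proportion = as.numeric(proportion),
      law = law)
}

.templateLaw <- function(name) {
  r <- .LAW_RANGES[[name]]
  new("DivisionLaw", mean = NA_real_, sd = NA_real_,
      supportLo = r$mean[1L], supportHi = r$mean[2L])
}

## Assemble the bounds matrix from a subpopulation structure: (k-1) free
## proportions (none for a singleton, whose proportion is fixed at 1), then
## division-time means, then sds, in subpopulation order.
.makeBounds <- function(subpops) {
  names <- vapply(subpops, function(s) s@name, character(1))
  k <- length(subpops)
  lo <- numeric(0); hi <- numeric(0); nm <- character(0)
  if (k > 1L) {
    free <- names[-k]
    lo <- c(lo, rep(0, k - 1L)); hi <- c(hi, rep(1, k - 1L))
    nm <- c(nm, paste0("p_", free))
  }
  dividing <- names[vapply(subpops, function(s) !is.null(s@law), logical(1))]
  for (d in dividing) {
    lo <- c(lo, .LAW_RANGES[[d]]$mean[1L]); hi <- c(hi, .LAW_RANGES[[d]]$mean[2L])
    nm <- c(nm, paste0("mean_", d))
  }
  for (d in dividing) {
    lo <- c(lo, .LAW_RANGES[[d]]$sd[1L]); hi <- c(hi, .LAW_RANGES[[d]]$sd[2L])
    nm <- c(nm, paste0("sd_", d))
  }
  matrix(c(lo, hi), ncol = 2L, dimnames = list(nm, c("lo", "hi")))
}

.newModel <- function(id, subpops) {
  new("ProliferationModel", modelId = as.integer(id), subpopulations = subpops,
      bounds = .makeBounds(subpops))
}

#' The four standard label-retention proliferation models
#'
#' Returns the four candidate population structures compared in the
#' label-retention analysis, as unparameterized templates carrying their box
#' search spaces:
#' \describe{
#'   \item{Model 1}{a single proliferating population (division-time mean
#'     searched in 21--504 h, sd in 0.01--40 h); its proportion is fixed at 1.}
#'   \item{Model 2}{a quiescent population (no division within the chase) plus
#'     one proliferating population (21--504 h, sd 0.01--40 h).}
#'   \item{Model 3}{quiescent + fast-proliferating (21--63 h, sd 0.01--30 h) +
#'     slow-proliferating (63--504 h, sd 0.01--40 h).}
#'   \item{Model 4}{fast- + slow-proliferating only, same ranges as model 3.}
#' }
#' All proportion bounds are (0, 1).
#'
#' @return list of four [ProliferationModel-class] templates, named
#'   \code{"1"} to \code{"4"}.
#' @examples
#' standardModels()[[2]]
#' @export
standardModels <- function() {
  m1 <- .newModel(1L, list(
    .newSubpop("proliferating", 1, .templateLaw("proliferating"))))
  m2 <- .newModel(2L, list(
    .newSubpop("quiescent"),
    .newSubpop("proliferating", law = .templateLaw("proliferating"))))
  m3 <- .newModel(3L, list(
    .newSubpop("quiescent"),
    .newSubpop("fast", law = .templateLaw("fast")),
    .newSubpop("slow", law = .templateLaw("slow"))))
  m4 <- .newModel(4L, list(
    .newSubpop("fast", law = .templateLaw("fast")),
    .newSubpop("slow", law = .templateLaw("slow"))))
  list("1" = m1, "2" = m2, "3" = m3, "4" = m4)
}

#' Number of free parameters of a model
#'
#' Counts \code{k - 1} free proportions for \code{k} subpopulations (a
#' fixed-proportion singleton contributes none; the last proportion is the
#' remainder) plus a (mean, sd) pair per non-quiescent subpopulation.
#'
#' @param model a [ProliferationModel-class].
#' @return integer count; equals \code{nrow(searchBounds(model))}.
#' @export
freeParameterCount <- function(model) {
  stopifnot(is(model, "ProliferationModel"))
  nrow(model@bounds)
}

.infeasibleError <- function(msg) {
  structure(class = c("flowDilution_infeasible", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Decode an optimizer vector into a parameterized model
#'
#' The vector layout is: free proportions of the first \code{k - 1}
#' subpopulations, then division-time means, then standard deviations, each in
#' subpopulation order (quiescent subpopulations contribute no mean/sd). The
#' last subpopulation's proportion is the remainder \code{1 - sum(others)}.
#'
#' @param vector numeric free-parameter vector, each element within the
#'   model's bounds.
#' @param model a [ProliferationModel-class] template (see [standardModels()]).
#' @return a fully parameterized [ProliferationModel-class] whose proportions
#'   sum to 1.
#' @section Errors: an out-of-bounds element raises an error naming the
#'   parameter; a negative remainder proportion raises a condition of class
#'   \code{"flowDilution_infeasible"} (treated as fitness \code{+Inf} during
#'   optimization).
#' @examples
#' m2 <- standardModels()[["2"]]
#' decodeParameters(c(0.31, 44.94, 19.71), m2)
#' @export
decodeParameters <- function(vector, model) {
  stopifnot(is(model, "ProliferationModel"))
  b <- model@bounds
  vector <- as.numeric(vector)
  if (length(vector) != nrow(b))
    stop(sprintf("expected %d parameters, got %d", nrow(b), length(vector)),
         call. = FALSE)
  bad <- which(vector < b[, "lo"] | vector > b[, "hi"])
  if (length(bad))
    stop(sprintf("parameter '%s' = %g outside bounds [%g, %g]",
                 rownames(b)[bad[1L]], vector[bad[1L]],
                 b[bad[1L], "lo"], b[bad[1L], "hi"]), call. = FALSE)
  subpops <- model@subpopulations
  k <- length(subpops)
  nProp <- if (k > 1L) k - 1L else 0L
  props <- if (k > 1L) vector[seq_len(nProp)] else 1
  remainder <- 1 - sum(props)
  if (k > 1L) {
    if (remainder < -1e-12)
      stop(.infeasibleError(sprintf(
        "free proportions sum to %g > 1; remainder proportion is negative",
        sum(props))))
    props <- c(props, max(0, remainder))
  }
  dividing <- which(vapply(subpops, function(s) !is.null(s@law), logical(1)))
  nd <- length(dividing)
  means <- vector[nProp + seq_len(nd)]
  sds <- vector[nProp + nd + seq_len(nd)]
  out <- subpops
  for (i in seq_len(k)) {
    sp <- subpops[[i]]
    sp@proportion <- props[i]
    if (!is.null(sp@law)) {
      j <- match(i, dividing)
      r <- .LAW_RANGES[[sp@name]]
      sp@law <- new("DivisionLaw", mean = means[j], sd = sds[j],
                    supportLo = r$mean[1L], supportHi = r$mean[2L])
    }
    out[[i]] <- sp
  }
  new("ProliferationModel", modelId = model@modelId, subpopulations = out,
      bounds = b)
}

#' Encode a parameterized model back into an optimizer vector
#'
#' The inverse of [decodeParameters()] on fully parameterized models:
#' \code{decodeParameters(encodeParameters(m), template)} reproduces \code{m}.
#'
#' @param model a fully parameterized [ProliferationModel-class].
#' @return numeric vector in optimizer layout.
#' @export
encodeParameters <- function(model) {
  stopifnot(is(model, "ProliferationModel"))
  subpops <- model@subpopulations
  k <- length(subpops)
  props <- vapply(subpops, function(s) s@proportion, numeric(1))
  if (anyNA(props)) stop("model is not fully parameterized", call. = FALSE)
  laws <- Filter(Negate(is.null), lapply(subpops, function(s) s@law))
  means <- vapply(laws, function(l) l@mean, numeric(1))
  sds <- vapply(laws, function(l) l@sd, numeric(1))
  c(if (k > 1L) props[-k], means, sds)
}

#' Validate a proliferation model, reporting violations without raising
#'
#' Checks the structural invariants of [ProliferationModel-class] and its
#' components: proportions within \[0, 1\] summing to 1 (tolerance 1e-9),
#' division-law means within their supports, positive supports, quiescent
#' subpopulations without laws. \code{NA} proportions or means (an
#' unparameterized template) are accepted.
#'
#' @param model a [ProliferationModel-class].
#' @return character vector of violation messages; empty when the model is
#'   valid (use \code{length(validateModel(m)) == 0}).
#' @export
validateModel <- function(model) {
  if (!is(model, "ProliferationModel"))
    return("not a ProliferationModel")
  v <- character(0)
  subpops <- model@subpopulations
  props <- vapply(subpops, function(s) s@proportion, numeric(1))
  if (!anyNA(props)) {
    if (any(props < 0 | props > 1))
      v <- c(v, "a subpopulation proportion lies outside [0, 1]")
    if (abs(sum(props) - 1) > 1e-9)
      v <- c(v, sprintf("proportions sum to %.12g, not 1", sum(props)))
  }
  for (sp in subpops) {
    if (identical(sp@name, "quiescent") && !is.null(sp@law))
      v <- c(v, "quiescent subpopulation carries a division law")
    if (!is.null(sp@law)) {
      l <- sp@law
      if (l@supportLo <= 0)
        v <- c(v, sprintf("%s: division-time support must be positive", sp@name))
      if (l@supportLo > l@supportHi)
        v <- c(v, sprintf("%s: supportLo exceeds supportHi", sp@name))
      if (!is.na(l@mean) && (l@mean < l@supportLo || l@mean > l@supportHi))
        v <- c(v, sprintf("%s: mean %g outside support [%g, %g]",
                          sp@name, l@mean, l@supportLo, l@supportHi))
      if (!is.na(l@sd) && l@sd < 0)
        v <- c(v, sprintf("%s: negative sd", sp@name))
    }
  }
  v
}

#' Serialize a model (with any parameters) to YAML or JSON
#'
#' @param model a [ProliferationModel-class].
#' @param path output file; format chosen by extension (\code{.yaml} /
#'   \code{.yml} or \code{.json}).
#' @return \code{writeModel} invisibly returns \code{path}; \code{readModel}
#'   returns the reconstructed [ProliferationModel-class].
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "ProliferationModel"))
  doc <- list(
    model_id = model@modelId,
    subpopulations = lapply(model@subpopulations, function(sp) {
      x <- list(name = sp@name, proportion = sp@proportion)
      if (!is.null(sp@law))
        x <- c(x, list(mean = sp@law@mean, sd = sp@law@sd,
                       support = c(sp@law@supportLo, sp@law@supportHi)))
      x
    }))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(doc, path)
  else
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  subpops <- lapply(doc$subpopulations, function(x) {
    law <- NULL
    if (!is.null(x$mean)) {
      sup <- unlist(x$support)
      law <- new("DivisionLaw",
                 mean = .asNum(x$mean), sd = .asNum(x$sd),
                 supportLo = as.numeric(sup[1L]), supportHi = as.numeric(sup[2L]))
    }
    .newSubpop(x$name, .asNum(x$proportion), law)
  })
  .newModel(doc$model_id, subpops)
}

.asNum <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
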