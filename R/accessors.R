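# Accessors: downstream code and user scripts go through these rather than
# reaching into slots.

#' @rdname VoiceSpace-class
#' @param object a `VoiceSpace`
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname VoiceSpace-class
#' @export
setMethod("coords", "VoiceSpace", function(object) object@coords)

#' @rdname VoiceSpace-class
#' @export
setGeneric("speakerIds", function(object) standardGeneric("speakerIds"))

#' @rdname VoiceSpace-class
#' @export
setMethod("speakerIds", "VoiceSpace", function(object) object@speakerIds)

#' @rdname ResponseMatrix-class
#' @param object a `ResponseMatrix`
#' @export
setGeneric("correctness", function(object) standardGeneric("correctness"))

#' @rdname ResponseMatrix-class
#' @export
setMethod("correctness", "ResponseMatrix", function(object) object@correctness)

#' @rdname ResponseMatrix-class
#' @export
setGeneric("responseTimes", function(object) standardGeneric("responseTimes"))

#' @rdname ResponseMatrix-class
#' @export
setMethod("responseTimes", "ResponseMatrix", function(object) {
  if (length(object@rt)) object@rt else NULL
})

#' @rdname ResponseMatrix-class
#' @export
setGeneric("personGroups", function(object) standardGeneric("personGroups"))

#' @rdname ResponseMatrix-class
#' @export
setMethod("personGroups", "ResponseMatrix", function(object) {
  if (ncol(object@groups)) object@groups else NULL
})

#' @rdname ResponseMatrix-class
#' @export
setGeneric("itemIds", function(object) standardGeneric("itemIds"))

#' @rdname ResponseMatrix-class
#' @export
setMethod("itemIds", "ResponseMatrix", function(object) colnames(object@correctness))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("personIds", function(object) standardGeneric("personIds"))

#' @rdname ResponseMatrix-class
#' @export
setMethod("personIds", "ResponseMatrix", function(object) rownames(object@correctness))

#' @rdname IRTFit-class
#' @param object an `IRTFit`
#' @export
setGeneric("itemParams", function(object) standardGeneric("itemParams"))

#' @rdname IRTFit-class
#' @export
setMethod("itemParams", "IRTFit", function(object) object@items)

#' @rdname IRTFit-class
#' @export
setGeneric("priorParams", function(object) standardGeneric("priorParams"))

#' @rdname IRTFit-class
#' @export
setMethod("priorParams", "IRTFit", function(object) object@prior)

#' Extract the marginal log-likelihood of a fit
#'
#' @param object an [IRTFit-class] object
#' @param ... ignored
#' @return a `logLik` object with `df` set to the free-parameter count, so
#'   `stats::AIC()`/`stats::BIC()` work on it.
#' @export
setMethod("logLik", "IRTFit", function(object, ...) {
  structure(object@loglik, df = object@npar, nobs = object@nPersons,
            class = "logLik")
})

#' @rdname TripletAssignment-class
#' @param object a `TripletAssignment`
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname TripletAssignment-class
#' @export
setMethod("assignments", "TripletAssignment", function(object) object@assignments)

#' @rdname TripletAssignment-class
#' @export
setGeneric("targetIds", function(object) standardGeneric("targetIds"))

#' @rdname TripletAssignment-class
#' @export
setMethod("targetIds", "TripletAssignment", function(object) object@targets)

#' @rdname TestBlueprint-class
#' @param object a `TestBlueprint`
#' @export
setGeneric("testTrials", function(object) standardGeneric("testTrials"))

#' @rdname TestBlueprint-class
#' @export
setMethod("testTrials", "TestBlueprint", function(object) object@test)

#' @rdname TestBlueprint-class
#' @export
setGeneric("learningTrials", function(object) standardGeneric("learningTrials"))

#' @rdname TestBlueprint-class
#' @export
setMethod("learningTrials", "TestBlueprint", function(object) {
  list(familiarization = object@familiarization, immediate = object@immediate)
})

#' @rdname TestBlueprint-class
#' @export
setGeneric("repetitionPlaylist", function(object) standardGeneric("repetitionPlaylist"))

#' @rdname TestBlueprint-class
#' @export
setMethod("repetitionPlaylist", "TestBlueprint", function(object) object@repetition)

#' @rdname SelectionTrace-class
#' @param object a `SelectionTrace`
#' @export
setGeneric("selectionLog", function(object) standardGeneric("selectionLog"))

#' @rdname SelectionTrace-class
#' @export
setMethod("selectionLog", "SelectionTrace", function(object) object@log)

#' @rdname SelectionTrace-class
#' @export
setGeneric("finalItems", function(object) standardGeneric("finalItems"))

#' @rdname SelectionTrace-class
#' @export
setMethod("finalItems", "SelectionTrace", function(object) object@finalItems)

#' @rdname ScoreReport-class
#' @param object a `ScoreReport`
#' @export
setGeneric("personScores", function(object) standardGeneric("personScores"))

#' @rdname ScoreReport-class
#' @export
setMethod("personScores", "ScoreReport", function(object) object@persons)

#' @rdname ScoreReport-class
#' @export
setGeneric("cohortSummary", function(object) standardGeneric("cohortSummary"))

#' @rdname ScoreReport-class
#' @export
setMethod("cohortSummary", "ScoreReport", function(object) object@cohort)
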