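#' @rdname CallRecording-class
#' @param object,x a CallRecording or CallSet.
#' @export
setGeneric("waveform", function(x) standardGeneric("waveform"))

#' @rdname CallRecording-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname CallSet-class
#' @export
setGeneric("callData", function(x) standardGeneric("callData"))

#' @rdname CallRecording-class
#' @export
setMethod("waveform", "CallRecording", function(x) x@waveform)

#' @rdname CallRecording-class
#' @export
setMethod("sampleRate", "CallRecording", function(x) x@sampleRate)

#' @rdname CallSet-class
#' @export
setMethod("callData", "CallSet", function(x) x@callData)

#' @rdname CallSet-class
#' @export
setMethod("length", "CallSet", function(x) length(x@calls))

#' @rdname CallSet-class
#' @param i index.
#' @export
setMethod("[[", "CallSet", function(x, i) x@calls[[i]])

setMethod("show", "CallRecording", function(object) {
  cat(sprintf(
    "CallRecording '%s': %.3f s @ %g Hz | pig %s (team %s, age %g d, class %d)\n  context: %s (%s)\n",
    object@callId, length(object@waveform) / object@sampleRate,
    object@sampleRate, object@pigId, object@teamId, object@ageDays,
    object@ageClass, object@context, object@valence))
})

setMethod("show", "CallSet", function(object) {
  md <- object@callData
  cat(sprintf("CallSet: %d calls, %d pigs, %d teams, %d contexts\n",
              length(object@calls), length(unique(md$pig_id)),
              length(unique(md$team_id)), length(unique(md$context))))
  if (nrow(md)) {
    tab <- table(md$valence)
    cat("  valence: ", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "PdfaResult", function(object) {
  cat(sprintf("PdfaResult (test factor: %s)\n", object@testFactor))
  cat(sprintf("  levels: %d | individuals: %d | calls: %d (selected %d)\n",
              object@nLevels, object@nIndividuals, object@nCallsTotal,
              object@nCallsSelected))
  cat(sprintf("  classified:       %.2f%% (chance %.2f%%, p = %.4g)\n",
              object@pctClassified, object@chanceClassified,
              object@pClassified))
  cat(sprintf("  cross-classified: %.2f%% (chance %.2f%%, p = %.4g)\n",
              object@pctCrossClassified, object@chanceCrossClassified,
              object@pCross))
  cat(sprintf("  relative cross-classification: %.2f\n",
              object@relativeCross))
})

setMethod("show", "EmbeddingResult", function(object) {
  cat(sprintf("EmbeddingResult: %d points, perplexity %g, seed %d\n",
              nrow(object@coords), object@perplexity, object@seed))
})
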