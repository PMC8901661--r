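#' CallRecording: one cropped vocalization
#'
#' Container for a single cropped call: the mono waveform, its sample rate,
#' and the per-call metadata used throughout the pipeline (pig identity,
#' recording team, age, context category and the valence attributed to that
#' context). For synthesized calls, `synthParams` keeps a copy of the
#' parameter draws that produced the waveform so that feature-recovery tests
#' can compare extracted against generated values.
#'
#' @slot callId character scalar, unique call identifier.
#' @slot waveform numeric vector of samples in [-1, 1] (full scale).
#' @slot sampleRate numeric scalar, Hz.
#' @slot pigId,teamId character scalars; pigs are nested within teams.
#' @slot ageDays numeric, age at recording in days.
#' @slot ageClass integer in 1:3 (1 = 1-25 d, 2 = 32-43 d, 3 = >= 85 d).
#' @slot context character, one of the context category labels.
#' @slot valence character, "negative" or "positive".
#' @slot synthParams list of generating parameter draws (empty for real
#'   recordings).
#'
#' @aliases CallRecording
#' @exportClass CallRecording
setClass("CallRecording",
  representation(
    callId = "character",
    waveform = "numeric",
    sampleRate = "numeric",
    pigId = "character",
    teamId = "character",
    ageDays = "numeric",
    ageClass = "integer",
    context = "character",
    valence = "character",
    synthParams = "list"
  ),
  prototype(synthParams = list())
)

.ageClassOf <- function(ageDays) {
  # class bounds: 1 = 1-25 d, 2 = 32-43 d, 3 = >= 85 d
  if (ageDays <= 25) 1L else if (ageDays >= 32 && ageDays <= 43) 2L
  else if (ageDays >= 85) 3L else NA_integer_
}

setValidity("CallRecording", function(object) {
  msg <- character()
  if (length(object@waveform) == 0L)
    msg <- c(msg, "waveform must be non-empty")
  if (!all(is.finite(object@waveform)))
    msg <- c(msg, "waveform must be finite")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a positive scalar")
  if (!object@valence %in% c("negative", "positive"))
    msg <- c(msg, "valence must be 'negative' or 'positive'")
  if (!object@ageClass %in% 1:3)
    msg <- c(msg, "ageClass must be 1, 2 or 3")
  expected <- .ageClassOf(object@ageDays)
  if (!is.na(expected) && expected != object@ageClass)
    msg <- c(msg, sprintf("ageClass %d inconsistent with ageDays %.0f",
                          object@ageClass, object@ageDays))
  if (length(msg)) msg else TRUE
})

#' CallSet: a collection of calls with a metadata table
#'
#' Holds a list of [CallRecording] objects together with a per-call
#' metadata `data.frame` (one row per call, in the same order). The table
#' is the tabular view used by the statistics and reporting stages.
#'
#' @slot calls list of CallRecording.
#' @slot callData data.frame with columns call_id, pig_id, team_id,
#'   age_days, age_class, context, valence.
#'
#' @aliases CallSet
#' @exportClass CallSet
setClass("CallSet",
  representation(calls = "list", callData = "data.frame")
)

setValidity("CallSet", function(object) {
  msg <- character()
  if (length(object@calls) != nrow(object@callData))
    msg <- c(msg, "one callData row is required per call")
  if (length(object@calls)) {
    if (!all(vapply(object@calls, is, logical(1), "CallRecording")))
      msg <- c(msg, "all elements of calls must be CallRecording")
    ids <- vapply(object@calls, function(x) x@callId, character(1))
    if (!identical(ids, as.character(object@callData$call_id)))
      msg <- c(msg, "callData$call_id must match call order")
  }
  need <- c("call_id", "pig_id", "team_id", "age_days", "age_class",
            "context", "valence")
  if (!all(need %in% names(object@callData)))
    msg <- c(msg, paste("callData must contain columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PdfaResult: permuted discriminant function analysis summary
#'
#' Observed and permutation-null classification results of a pDFA run:
#' percentage of derivation calls classified and of held-out calls
#' cross-classified to the correct test-factor level, the corresponding
#' chance levels (permuted percentages averaged across permutations),
#' permutation p-values, the relative cross-classification ratio, and the
#' dataset bookkeeping counts.
#'
#' @slot testFactor character, "valence" or "context".
#' @slot nLevels,nIndividuals,nCallsTotal,nCallsSelected integer counts.
#'   `nCallsTotal` counts complete-case calls entering the analysis;
#'   `nCallsSelected` is the size of one balanced derivation set.
#' @slot pctClassified,chanceClassified,pctCrossClassified,chanceCrossClassified
#'   percentages in [0, 100].
#' @slot pClassified,pCross permutation p-values in (0, 1].
#' @slot relativeCross ratio pctCrossClassified / chanceCrossClassified.
#' @slot permutedClassified,permutedCross numeric vectors, the permutation
#'   null distributions.
#' @slot design list, the design settings used (reps, permutations, seed).
#'
#' @aliases PdfaResult
#' @exportClass PdfaResult
setClass("PdfaResult",
  representation(
    testFactor = "character",
    nLevels = "integer",
    nIndividuals = "integer",
    nCallsTotal = "integer",
    nCallsSelected = "integer",
    pctClassified = "numeric",
    chanceClassified = "numeric",
    pClassified = "numeric",
    pctCrossClassified = "numeric",
    chanceCrossClassified = "numeric",
    relativeCross = "numeric",
    pCross = "numeric",
    permutedClassified = "numeric",
    permutedCross = "numeric",
    design = "list"
  )
)

setValidity("PdfaResult", function(object) {
  msg <- character()
  pcts <- c(object@pctClassified, object@chanceClassified,
            object@pctCrossClassified, object@chanceCrossClassified)
  if (any(pcts < 0 | pcts > 100)) msg <- c(msg, "percentages must be in [0, 100]")
  ps <- c(object@pClassified, object@pCross)
  if (any(ps <= 0 | ps > 1)) msg <- c(msg, "p-values must be in (0, 1]")
  if (object@nCallsSelected > object@nCallsTotal)
    msg <- c(msg, "nCallsSelected cannot exceed nCallsTotal")
  if (object@chanceCrossClassified > 0) {
    rc <- object@pctCrossClassified / object@chanceCrossClassified
    if (abs(rc - object@relativeCross) > 1e-8)
      msg <- c(msg, "relativeCross must equal pctCross/chanceCross")
  }
  if (length(msg)) msg else TRUE
})

#' EmbeddingResult: 2-D t-SNE map of classifier activations
#'
#' @slot coords n x 2 numeric matrix of embedding coordinates.
#' @slot labels data.frame with per-point valence and context labels (and
#'   call_id when available).
#' @slot perplexity numeric, the t-SNE perplexity used.
#' @slot seed integer, RNG seed used for the embedding.
#'
#' @aliases EmbeddingResult
#' @exportClass EmbeddingResult
setClass("EmbeddingResult",
  representation(
    coords = "matrix",
    labels = "data.frame",
    perplexity = "numeric",
    seed = "integer"
  )
)

setValidity("EmbeddingResult", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (nrow(object@coords) != nrow(object@labels))
    msg <- c(msg, "one label row per embedded point is required")
  if (object@perplexity >= nrow(object@coords))
    msg <- c(msg, "perplexity must be smaller than the number of points")
  if (length(msg)) msg else TRUE
})
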