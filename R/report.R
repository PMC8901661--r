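# Cross-call-type aggregation and dataset accounting: the arithmetic used
# to report pDFA results as weighted averages across LF and HF calls.

#' Weighted average of per-call-type percentages
#'
#' `(v1 w1 + v2 w2 + ...) / (w1 + w2 + ...)`, with call counts as
#' weights. Used to combine LF and HF classification percentages into
#' the single figures reported for the whole dataset; rounding happens
#' only at presentation.
#'
#' @param values numeric vector (e.g. percentages per call type).
#' @param weights positive call counts, same length.
#' @return the weighted average.
#' @examples
#' weightedAverage(c(61.25, 63.18), c(5391, 1832))  # -> 61.74
#' @export
weightedAverage <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (any(weights <= 0)) stop("weights must be positive")
  sum(values * weights) / sum(weights)
}

#' Relative (cross-)classification level
#'
#' Ratio of the cross-classified percentage to its permutation chance
#' level; 1 means chance performance. Presented to 2 decimal places.
#'
#' @param pctCross cross-classification percentage.
#' @param chanceCross chance level percentage (> 0).
#' @return the ratio.
#' @export
relativeClassification <- function(pctCross, chanceCross) {
  if (any(chanceCross <= 0)) stop("chance level must be positive")
  pctCross / chanceCross
}

#' Dataset accounting
#'
#' Calls included in an analysis after exclusions (e.g. calls whose
#' amplitude-modulation rate could not be measured).
#'
#' @param total total calls in the dataset.
#' @param excluded calls excluded (<= total).
#' @return included call count.
#' @export
datasetAccounting <- function(total, excluded) {
  if (excluded > total) stop("cannot exclude more calls than exist")
  total - excluded
}

#' Aggregate per-call-type pDFA results across LF and HF
#'
#' Combines two [PdfaResult-class] objects into the dataset-level report:
#' weighted averages (weights = complete-case call counts per call type)
#' of the classified and cross-classified percentages and their chance
#' levels, the relative cross-classification ratios, and the dataset
#' accounting.
#'
#' @param lf,hf [PdfaResult-class] for LF and HF calls.
#' @param totalCalls total calls in the dataset before exclusions
#'   (default: sum of the two analyses' complete-case counts).
#' @return list of class `AggregateReport`.
#' @export
aggregatePdfa <- function(lf, hf, totalCalls = NULL) {
  stopifnot(is(lf, "PdfaResult"), is(hf, "PdfaResult"))
  w <- c(lf@nCallsTotal, hf@nCallsTotal)
  included <- sum(w)
  if (is.null(totalCalls)) totalCalls <- included
  out <- list(
    perCallType = list(LF = pdfaReport(lf), HF = pdfaReport(hf)),
    weights = c(LF = w[1L], HF = w[2L]),
    weighted = list(
      classified = weightedAverage(c(lf@pctClassified, hf@pctClassified), w),
      chance_classified = weightedAverage(
        c(lf@chanceClassified, hf@chanceClassified), w),
      cross_classified = weightedAverage(
        c(lf@pctCrossClassified, hf@pctCrossClassified), w),
      chance_cross_classified = weightedAverage(
        c(lf@chanceCrossClassified, hf@chanceCrossClassified), w)
    ),
    relativeCross = c(LF = lf@relativeCross, HF = hf@relativeCross),
    accounting = list(total = totalCalls,
                      excluded = totalCalls - included,
                      included = included)
  )
  class(out) <- "AggregateReport"
  out
}

#' @export
print.AggregateReport <- function(x, ...) {
  cat("AggregateReport (weighted across LF and HF)\n")
  cat(sprintf("  classified:       %.1f%% (chance %.1f%%)\n",
              x$weighted$classified, x$weighted$chance_classified))
  cat(sprintf("  cross-classified: %.1f%% (chance %.1f%%)\n",
              x$weighted$cross_classified,
              x$weighted$chance_cross_classified))
  cat(sprintf("  relative cross-classification: LF %.2f, HF %.2f\n",
              x$relativeCross["LF"], x$relativeCross["HF"]))
  cat(sprintf("  calls: %d total, %d excluded, %d included\n",
              x$accounting$total, x$accounting$excluded,
              x$accounting$included))
  invisible(x)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates a synthetic dataset, extracts the acoustic feature table,
#' screens parameters (PCA + valence mixed models per call type), runs
#' the valence pDFA per call type with cross-call-type aggregation, and
#' optionally trains the spectrogram classifier and computes its t-SNE
#' activation map. Every stage derives its seed from `seed`; re-running
#' with the same arguments reproduces all outputs.
#'
#' @param spec a [synthSpec()]; its `rngSeed` is overridden by `seed`.
#' @param nCalls dataset size.
#' @param seed master seed.
#' @param pdfaPermutations permutations per pDFA.
#' @param cnn logical: train the spectrogram classifier and embed its
#'   activations.
#' @param cnnTrials,cnnEpochs scaled-down training protocol for the
#'   optional classifier stage.
#' @param spectrogram a [spectrogramConfig()] for the classifier stage.
#' @param outDir optional directory; when given, the feature table
#'   (features.csv), pDFA reports (pdfa_<type>.json), the aggregate
#'   report (report.json) and the embedding (embedding.csv/.png) are
#'   written there.
#' @return list with `features`, `selection` (per call type), `lmm` (per
#'   call type, Dur model), `pdfa` (per call type), `aggregate`, and —
#'   when `cnn` — `cnnMetrics` and `embedding`.
#' @export
runPipeline <- function(spec = synthSpec(), nCalls = 400, seed = 1L,
                        pdfaPermutations = 200L, cnn = FALSE,
                        cnnTrials = 2L, cnnEpochs = 6L,
                        spectrogram = spectrogramConfig(
                          overlap = 0.75, resolution = c(32, 32)),
                        outDir = NULL) {
  spec$rngSeed <- as.integer(seed)
  # regenerate the pig roster under the master seed
  spec <- synthSpec(nPigs = spec$nPigs, nTeams = spec$nTeams,
                    ageClassProbs = spec$ageClassProbs,
                    contexts = spec$contexts, cellParams = spec$cellParams,
                    lfProb = spec$lfProb, pigLogDurSd = spec$pigLogDurSd,
                    pigLogCenterSd = spec$pigLogCenterSd,
                    sampleRate = spec$sampleRate, rngSeed = seed)
  calls <- synthesizeDataset(spec, nCalls = nCalls)
  features <- extractFeatures(calls)
  out <- list(features = features)
  out$selection <- lapply(c(LF = "LF", HF = "HF"), function(ty)
    tryCatch(selectParameters(features, ty), error = function(e) NULL))
  out$lmm <- lapply(c(LF = "LF", HF = "HF"), function(ty) {
    rows <- features[features$call_type == ty, ]
    tryCatch(fitValenceLmm(rows, "Dur", "valence"),
             error = function(e) NULL)
  })
  out$pdfa <- lapply(c(LF = "LF", HF = "HF"), function(ty) {
    design <- pdfaDesign("valence", nPermutations = pdfaPermutations,
                         rngSeed = seed + match(ty, c("LF", "HF")))
    # a small dataset may lack one valence within a call type; report
    # that type as unavailable rather than failing the run
    tryCatch(runPdfa(features[features$call_type == ty, ], design),
             error = function(e) {
               warning("pDFA skipped for ", ty, " calls: ",
                       conditionMessage(e))
               NULL
             })
  })
  out$aggregate <- if (!is.null(out$pdfa$LF) && !is.null(out$pdfa$HF))
    aggregatePdfa(out$pdfa$LF, out$pdfa$HF, totalCalls = nrow(features))
  if (cnn) {
    cfg <- trainConfig("valence", epochs = cnnEpochs, nTrials = cnnTrials,
                       rngSeed = seed)
    imgs <- spectrogramTensor(calls, spectrogram)
    fit <- trainClassifier(imgs, features$valence, cfg)
    out$cnnMetrics <- fit$trials
    out$cnnSummary <- fit$summary
    act <- extractActivations(fit$model, imgs)
    perp <- min(30, floor((nrow(act) - 1) / 3))
    out$embedding <- embedActivations(
      act, features[, c("call_id", "valence", "context")],
      perplexity = perp, seed = seed)
  }
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeFeatures(features, file.path(outDir, "features.csv"))
    for (ty in c("LF", "HF")) if (!is.null(out$pdfa[[ty]]))
      pdfaReport(out$pdfa[[ty]], file.path(outDir,
                                           paste0("pdfa_", ty, ".json")))
    if (!is.null(out$aggregate)) {
      rep <- out$aggregate
      rep$perCallType <- NULL
      jsonlite::write_json(rep, file.path(outDir, "report.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    if (!is.null(out$embedding))
      writeEmbedding(out$embedding, file.path(outDir, "embedding.csv"),
                     file.path(outDir, "embedding.png"))
  }
  out
}
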