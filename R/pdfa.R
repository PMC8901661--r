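# Permuted discriminant function analysis with a control factor.
#
# The test factor (valence or context) is evaluated by linear DFA on a
# balanced derivation subset; held-out calls give the cross-classification
# percentage. Significance is assessed against a permutation null in which
# test-factor labels are shuffled only WITHIN pigs, so that individual
# identity (the control factor) can never masquerade as a valence or
# context effect.

#' Design of a pDFA run
#'
#' @param testFactor "valence" or "context".
#' @param features character vector of feature columns used by the
#'   discriminant functions (default the four screening parameters).
#' @param nSelectionReps number of random balanced derivation-set draws
#'   averaged into the observed statistic.
#' @param nPermutations number of label permutations for the null
#'   distribution (>= 100).
#' @param minCallsPerCell calls drawn from each eligible (pig x level)
#'   cell into the derivation set.
#' @param rngSeed integer seed.
#' @return validated list of class `PdfaDesign`.
#' @export
pdfaDesign <- function(testFactor = c("valence", "context"),
                       features = c("Dur", "AmpModRate", "Q50",
                                    "WienEntropy"),
                       nSelectionReps = 100L, nPermutations = 1000L,
                       minCallsPerCell = 2L, rngSeed = 1L) {
  testFactor <- match.arg(testFactor)
  stopifnot(nPermutations >= 100L, minCallsPerCell >= 1L,
            nSelectionReps >= 1L, length(features) >= 1L)
  out <- list(testFactor = testFactor, features = features,
              nSelectionReps = as.integer(nSelectionReps),
              nPermutations = as.integer(nPermutations),
              minCallsPerCell = as.integer(minCallsPerCell),
              rngSeed = as.integer(rngSeed))
  class(out) <- "PdfaDesign"
  out
}

#' Build the (pig x test level) cell map of a feature table
#'
#' Drops rows with missing values in the design's feature columns
#' (reporting the count), then maps each (pig, test-factor level) cell to
#' its row indices and flags which pigs span at least two test levels (the
#' crossed portion of the incomplete design).
#'
#' @param features feature table.
#' @param design a [pdfaDesign()].
#' @return list with `cells` (data.frame pig/level/n plus a list column of
#'   row indices), `rows` (complete-case row indices into `features`),
#'   `labels`, `pigs`, `levels`, `crossedPigs`, `nDropped`.
#' @export
buildCells <- function(features, design) {
  stopifnot(inherits(design, "PdfaDesign"),
            all(design$features %in% names(features)))
  ok <- complete.cases(features[, design$features, drop = FALSE])
  rows <- which(ok)
  labels <- as.character(features[[design$testFactor]][rows])
  pigs <- as.character(features$pig_id[rows])
  levels <- sort(unique(labels))
  if (length(levels) < 2L)
    stop("fewer than 2 levels of ", design$testFactor, " present")
  key <- paste(pigs, labels, sep = "\r")
  idx <- split(seq_along(rows), key)
  parts <- strsplit(names(idx), "\r", fixed = TRUE)
  cells <- data.frame(
    pig = vapply(parts, `[`, character(1), 1L),
    level = vapply(parts, `[`, character(1), 2L),
    n = lengths(idx),
    stringsAsFactors = FALSE
  )
  cells$rows <- unname(idx)   # indices into `rows` (complete-case space)
  perPig <- tapply(cells$level, cells$pig, function(x) length(unique(x)))
  list(cells = cells, rows = rows, labels = labels, pigs = pigs,
       levels = levels,
       crossedPigs = names(perPig)[perPig >= 2L],
       nDropped = sum(!ok))
}

# cells eligible for the derivation set: >= min calls, pig crossed with
# respect to eligibility (>= 2 levels each having an eligible cell)
.eligibleCells <- function(cellMap, minCalls) {
  cells <- cellMap$cells
  elig <- cells[cells$n >= minCalls, , drop = FALSE]
  perPig <- tapply(elig$level, elig$pig, function(x) length(unique(x)))
  keep <- names(perPig)[perPig >= 2L]
  elig[elig$pig %in% keep, , drop = FALSE]
}

#' Draw one balanced derivation / holdout split
#'
#' From every eligible cell (a pig x test-level combination with at least
#' `minCallsPerCell` complete-case calls, restricted to pigs with two or
#' more such levels) exactly `minCallsPerCell` calls are drawn without
#' replacement into the derivation set; every remaining complete-case
#' call forms the holdout. The derivation set is therefore balanced
#' across test levels within each contributing pig.
#'
#' @param cellMap output of [buildCells()].
#' @param design a [pdfaDesign()].
#' @return list with `derivation` and `holdout` (indices into the
#'   complete-case space, i.e. positions in `cellMap$rows`).
#' @export
balancedSelection <- function(cellMap, design) {
  elig <- .eligibleCells(cellMap, design$minCallsPerCell)
  if (!all(cellMap$levels %in% elig$level))
    stop("no eligible cell for test level(s): ",
         paste(setdiff(cellMap$levels, elig$level), collapse = ", "))
  deriv <- unlist(lapply(elig$rows, function(r) {
    if (length(r) == design$minCallsPerCell) r
    else sample(r, design$minCallsPerCell)
  }), use.names = FALSE)
  all_idx <- seq_along(cellMap$rows)
  list(derivation = sort(deriv), holdout = setdiff(all_idx, deriv))
}

# Ridge-regularized pooled-covariance LDA fallback (equal priors):
# classify by Mahalanobis distance to class means in the pooled metric.
.ridgeLda <- function(X, y, newX, eps = 1e-6) {
  lev <- sort(unique(y))
  mus <- t(vapply(lev, function(l) colMeans(X[y == l, , drop = FALSE]),
                  numeric(ncol(X))))
  Sp <- Reduce(`+`, lapply(lev, function(l) {
    Xi <- X[y == l, , drop = FALSE]
    crossprod(scale(Xi, center = TRUE, scale = FALSE))
  })) / (nrow(X) - length(lev))
  Sp <- Sp + diag(eps * sum(diag(Sp)) / ncol(X), ncol(X))
  Si <- solve(Sp)
  d2 <- vapply(seq_along(lev), function(k) {
    dx <- sweep(newX, 2L, mus[k, ])
    rowSums((dx %*% Si) * dx)
  }, numeric(nrow(newX)))
  lev[max.col(-d2, ties.method = "first")]
}

#' Linear discriminant classification of a derivation/holdout split
#'
#' Linear DFA with pooled covariance and equal priors across test levels
#' (priors must not re-encode class imbalance, since chance is estimated
#' empirically by permutation). Returns percent correct on the derivation
#' set ("classified") and on the holdout ("cross-classified"). A singular
#' pooled covariance triggers a ridge-regularized fallback with a
#' warning.
#'
#' @param X numeric feature matrix (complete cases).
#' @param labels test-factor labels.
#' @param derivation,holdout row index vectors.
#' @return named numeric `c(classified =, crossClassified =)`, percents.
#' @export
dfaClassify <- function(X, labels, derivation, holdout) {
  Xd <- X[derivation, , drop = FALSE]
  yd <- labels[derivation]
  stopifnot(length(unique(yd)) >= 2L,
            nrow(Xd) > ncol(Xd) + length(unique(yd)))
  k <- length(unique(yd))
  fit <- tryCatch(
    MASS::lda(Xd, grouping = base::factor(yd), prior = rep(1 / k, k)),
    error = function(e) NULL)
  predLab <- function(newX) {
    if (is.null(fit)) .ridgeLda(Xd, yd, newX)
    else as.character(predict(fit, newX)$class)
  }
  if (is.null(fit))
    warning("singular pooled covariance: using ridge-regularized LDA")
  pc <- 100 * mean(predLab(Xd) == yd)
  ph <- if (length(holdout))
    100 * mean(predLab(X[holdout, , drop = FALSE]) == labels[holdout])
  else NA_real_
  c(classified = pc, crossClassified = ph)
}

# permute test labels within each pig (the crossed permutation scheme:
# calls never move between pigs; single-level pigs keep their labels
# automatically)
.permuteWithinPigs <- function(labels, pigs) {
  out <- labels
  for (idx in split(seq_along(labels), pigs)) {
    if (length(idx) > 1L) out[idx] <- labels[sample(idx)]
  }
  out
}

#' Run a permuted discriminant function analysis
#'
#' The observed statistic is the mean over `nSelectionReps` random
#' balanced selections of the derivation-set and holdout classification
#' percentages. The null distribution permutes test-factor labels within
#' pigs (`nPermutations` times; one balanced selection and classification
#' per permutation); the chance level is the permuted percentage averaged
#' across permutations and p-values use the add-one convention
#' `(count(permuted >= observed) + 1) / (nPermutations + 1)`.
#'
#' @param features feature table from [extractFeatures()].
#' @param design a [pdfaDesign()].
#' @return a [PdfaResult-class].
#' @export
runPdfa <- function(features, design) {
  stopifnot(inherits(design, "PdfaDesign"))
  set.seed(design$rngSeed)
  cellMap <- buildCells(features, design)
  X <- as.matrix(features[cellMap$rows, design$features, drop = FALSE])
  labels <- cellMap$labels

  obs <- vapply(seq_len(design$nSelectionReps), function(i) {
    sel <- balancedSelection(cellMap, design)
    dfaClassify(X, labels, sel$derivation, sel$holdout)
  }, numeric(2))
  obsClassified <- mean(obs["classified", ])
  obsCross <- mean(obs["crossClassified", ])

  onePermutation <- function() {
    permLabels <- .permuteWithinPigs(labels, cellMap$pigs)
    permMap <- cellMap
    key <- paste(cellMap$pigs, permLabels, sep = "\r")
    idx <- split(seq_along(permLabels), key)
    parts <- strsplit(names(idx), "\r", fixed = TRUE)
    permMap$cells <- data.frame(
      pig = vapply(parts, `[`, character(1), 1L),
      level = vapply(parts, `[`, character(1), 2L),
      n = lengths(idx), stringsAsFactors = FALSE)
    permMap$cells$rows <- unname(idx)
    permMap$labels <- permLabels
    sel <- balancedSelection(permMap, design)
    dfaClassify(X, permLabels, sel$derivation, sel$holdout)
  }
  perm <- vapply(seq_len(design$nPermutations), function(i) {
    # a permutation can spread a rare level too thin for any eligible
    # cell; such label arrangements are re-drawn (bounded)
    for (try in 1:20) {
      res <- tryCatch(onePermutation(), error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    stop("could not find a permutable label arrangement with eligible cells")
  }, numeric(2))

  sel1 <- balancedSelection(cellMap, design)
  pVal <- function(permuted, observed)
    (sum(permuted >= observed) + 1) / (design$nPermutations + 1)
  chanceCross <- mean(perm["crossClassified", ])
  new("PdfaResult",
      testFactor = design$testFactor,
      nLevels = length(cellMap$levels),
      nIndividuals = length(unique(cellMap$pigs)),
      nCallsTotal = length(cellMap$rows),
      nCallsSelected = length(sel1$derivation),
      pctClassified = obsClassified,
      chanceClassified = mean(perm["classified", ]),
      pClassified = pVal(perm["classified", ], obsClassified),
      pctCrossClassified = obsCross,
      chanceCrossClassified = chanceCross,
      relativeCross = obsCross / chanceCross,
      pCross = pVal(perm["crossClassified", ], obsCross),
      permutedClassified = perm["classified", ],
      permutedCross = perm["crossClassified", ],
      design = list(features = design$features,
                    nSelectionReps = design$nSelectionReps,
                    nPermutations = design$nPermutations,
                    minCallsPerCell = design$minCallsPerCell,
                    rngSeed = design$rngSeed,
                    nDropped = cellMap$nDropped))
}

#' Export a PdfaResult as a JSON-ready list
#'
#' Mirrors the published summary-table layout: counts, percentages,
#' chance levels, relative cross-classification and p-values, plus a
#' provenance block with the seed, selection reps and permutation count.
#'
#' @param result a [PdfaResult-class].
#' @param path optional path; when given, JSON is written there.
#' @return the list, invisibly when `path` is given.
#' @export
pdfaReport <- function(result, path = NULL) {
  stopifnot(is(result, "PdfaResult"))
  out <- list(
    test_factor = result@testFactor,
    n_levels = result@nLevels,
    n_individuals = result@nIndividuals,
    n_calls_total = result@nCallsTotal,
    n_calls_selected = result@nCallsSelected,
    pct_classified = result@pctClassified,
    chance_classified = result@chanceClassified,
    p_classified = result@pClassified,
    pct_cross_classified = result@pctCrossClassified,
    chance_cross_classified = result@chanceCrossClassified,
    relative_cross_classification = result@relativeCross,
    p_cross_classified = result@pCross,
    provenance = result@design
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
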