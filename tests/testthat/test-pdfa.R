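# small deterministic feature table builder
pdfaToy <- function(pigs, valences, callsPerCell, sep = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(pig = pigs, valence = valences,
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    k <- callsPerCell
    data.frame(pig_id = grid$pig[i], valence = grid$valence[i],
               Dur = rnorm(k) + sep * (grid$valence[i] == "positive"),
               AmpModRate = rnorm(k), Q50 = rnorm(k),
               WienEntropy = rnorm(k), stringsAsFactors = FALSE)
  }))
  rows$call_id <- sprintf("c%04d", seq_len(nrow(rows)))
  rows$team_id <- "team1"; rows$age_class <- 1L; rows$context <- "x"
  rows$call_type <- "LF"
  rows
}

test_that("cell map bookkeeping is exact", {
  ft <- pdfaToy(c("p1", "p2"), c("negative", "positive"), 3)
  design <- pdfaDesign("valence", nPermutations = 100)
  cm <- buildCells(ft, design)
  expect_equal(nrow(cm$cells), 4)
  expect_true(all(cm$cells$n == 3))
  expect_setequal(cm$crossedPigs, c("p1", "p2"))
  expect_equal(cm$nDropped, 0)
  # a pig seen in one valence only is not crossed
  ft2 <- rbind(ft, pdfaToy("p3", "negative", 4, seed = 2))
  cm2 <- buildCells(ft2, design)
  expect_false("p3" %in% cm2$crossedPigs)
  expect_equal(sum(cm2$cells$pig == "p3"), 1)
  # dropping incomplete rows shrinks the right cells
  ft3 <- ft
  ft3$AmpModRate[c(1, 2, 4)] <- NA   # three calls of p1/negative-ish rows
  cm3 <- buildCells(ft3, design)
  expect_equal(cm3$nDropped, 3)
  expect_equal(length(cm3$rows), nrow(ft) - 3)
  expect_equal(sum(cm3$cells$n), nrow(ft) - 3)
  # single level errors
  expect_error(buildCells(ft[ft$valence == "negative", ], design),
               "fewer than 2 levels")
})

test_that("balanced selection draws min calls per eligible cell", {
  ft <- pdfaToy(c("p1", "p2"), c("negative", "positive"), 3)
  design <- pdfaDesign("valence", nPermutations = 100,
                       minCallsPerCell = 2L)
  cm <- buildCells(ft, design)
  set.seed(1)
  sel <- balancedSelection(cm, design)
  expect_length(sel$derivation, 8)   # 4 cells x 2
  expect_length(sel$holdout, nrow(ft) - 8)
  expect_length(intersect(sel$derivation, sel$holdout), 0)
  # derivation is balanced across levels within pigs
  lab <- cm$labels[sel$derivation]
  pig <- cm$pigs[sel$derivation]
  expect_true(all(table(pig, lab) == 2))
  # a cell with exactly min calls is taken whole
  ft2 <- pdfaToy(c("p1", "p2"), c("negative", "positive"), 2)
  cm2 <- buildCells(ft2, design)
  sel2 <- balancedSelection(cm2, design)
  expect_length(sel2$derivation, 8)
  expect_length(sel2$holdout, 0)
  # different RNG states give different but equally sized draws
  set.seed(10); a <- balancedSelection(cm, design)
  set.seed(20); b <- balancedSelection(cm, design)
  expect_length(a$derivation, length(b$derivation))
  expect_false(identical(a$derivation, b$derivation))
})

test_that("LDA classification matches the whitened nearest-mean oracle", {
  # 3 classes, hand-checkable: equal priors LDA with pooled covariance is
  # nearest class mean in the whitened metric
  set.seed(4)
  X <- rbind(matrix(rnorm(20, 0), 10, 2),
             matrix(rnorm(20, 3), 10, 2),
             matrix(rnorm(20, c(0, 6)), 10, 2))
  y <- rep(c("a", "b", "c"), each = 10)
  deriv <- seq(1, 30, by = 2); hold <- seq(2, 30, by = 2)
  got <- dfaClassify(X, y, deriv, hold)
  # oracle: whiten by pooled covariance of the derivation set
  Xd <- X[deriv, ]; yd <- y[deriv]
  mus <- rbind(colMeans(Xd[yd == "a", ]), colMeans(Xd[yd == "b", ]),
               colMeans(Xd[yd == "c", ]))
  Sp <- Reduce(`+`, lapply(c("a", "b", "c"), function(l)
    crossprod(scale(Xd[yd == l, ], scale = FALSE)))) / (nrow(Xd) - 3)
  Si <- solve(Sp)
  nearest <- function(M) {
    apply(M, 1, function(x) {
      d2 <- rowSums(((rep(1, 3) %o% x) - mus) %*% Si *
                      ((rep(1, 3) %o% x) - mus))
      c("a", "b", "c")[which.min(d2)]
    })
  }
  expect_equal(unname(got["classified"]),
               100 * mean(nearest(Xd) == yd))
  expect_equal(unname(got["crossClassified"]),
               100 * mean(nearest(X[hold, ]) == y[hold]))
})

test_that("well separated classes classify perfectly; null is at chance", {
  set.seed(9)
  Xsep <- rbind(matrix(rnorm(40), 20, 2),
                matrix(rnorm(40, 10), 20, 2))
  y <- rep(c("neg", "pos"), each = 20)
  res <- dfaClassify(Xsep, y, 1:40, integer(0))
  expect_equal(unname(res["classified"]), 100)
  # labels independent of features: holdout near 50% in expectation
  set.seed(10)
  accs <- replicate(40, {
    X <- matrix(rnorm(200), 100, 2)
    y <- sample(rep(c("a", "b"), 50))
    dfaClassify(X, y, 1:60, 61:100)["crossClassified"]
  })
  expect_lt(abs(mean(accs) - 50), 4)
})

test_that("permutation never moves calls between pigs", {
  ft <- pdfaToy(paste0("p", 1:6), c("negative", "positive"), 4)
  pigs <- ft$pig_id
  set.seed(3)
  for (i in 1:20) {
    perm <- vocalence:::.permuteWithinPigs(ft$valence, pigs)
    for (p in unique(pigs))
      expect_equal(sort(perm[pigs == p]), sort(ft$valence[pigs == p]))
  }
})

test_that("pDFA on separated data attains the minimum p-value", {
  ft <- pdfaToy(paste0("p", 1:6), c("negative", "positive"), 6, sep = 10)
  design <- pdfaDesign("valence", nSelectionReps = 5,
                       nPermutations = 199, rngSeed = 7L)
  res <- runPdfa(ft, design)
  expect_equal(res@pCross, 1 / 200)
  expect_equal(res@pClassified, 1 / 200)
  expect_gt(res@pctCrossClassified, 95)
  expect_equal(res@relativeCross,
               res@pctCrossClassified / res@chanceCrossClassified)
  expect_equal(res@nLevels, 2L)
  expect_equal(res@nIndividuals, 6L)
})

test_that("pDFA is deterministic given its seed", {
  ft <- pdfaToy(paste0("p", 1:5), c("negative", "positive"), 5, sep = 1)
  design <- pdfaDesign("valence", nSelectionReps = 3,
                       nPermutations = 100, rngSeed = 42L)
  a <- runPdfa(ft, design)
  b <- runPdfa(ft, design)
  expect_identical(a@pctCrossClassified, b@pctCrossClassified)
  expect_identical(a@permutedCross, b@permutedCross)
  expect_identical(a@pCross, b@pCross)
})

test_that("chance level of a balanced 2-level null is near 50", {
  ft <- nullPdfaFeatures(314)
  design <- pdfaDesign("valence", nSelectionReps = 5,
                       nPermutations = 300, rngSeed = 15L)
  res <- runPdfa(ft, design)
  expect_lt(abs(res@chanceCrossClassified - 50), 2)
})

test_that("stronger separation does not reduce cross-classification", {
  design <- pdfaDesign("valence", nSelectionReps = 10,
                       nPermutations = 100, rngSeed = 5L)
  pcts <- vapply(c(0, 1.5, 4), function(sep) {
    ft <- pdfaToy(paste0("p", 1:8), c("negative", "positive"), 8,
                  sep = sep, seed = 100)
    runPdfa(ft, design)@pctCrossClassified
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("missing-feature rows are dropped and reported end to end", {
  ft <- pdfaToy(paste0("p", 1:4), c("negative", "positive"), 6)
  ft$AmpModRate[1:5] <- NA
  design <- pdfaDesign("valence", nSelectionReps = 3,
                       nPermutations = 100, rngSeed = 2L)
  res <- runPdfa(ft, design)
  expect_equal(res@design$nDropped, 5)
  expect_equal(res@nCallsTotal, nrow(ft) - 5)
  rep <- pdfaReport(res)
  expect_equal(rep$n_calls_total, nrow(ft) - 5)
  expect_equal(rep$provenance$nPermutations, 100L)
})
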