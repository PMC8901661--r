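# constructed-covariance oracle: a single shared factor on which each
# category has one strongly aligned parameter and weaker echoes; the
# sample covariance is made EXACTLY equal to the target (mvrnorm
# empirical), so the factor component is the only eigenvalue > 1 and
# loadings are proportional to the factor alignments by construction
latentFeatureTable <- function(n = 300, seed = 1) {
  set.seed(seed)
  params <- c(Dur = 0.90, AmpVar = 0.40, AmpModRate = 0.85,
              AmpModExtent = 0.30, Q25 = 0.45, Q50 = 0.80, Q75 = 0.40,
              FPeak = 0.30, Harmonicity = 0.35, WienEntropy = 0.75)
  sigma <- tcrossprod(params) + diag(1 - params^2)
  X <- MASS::mvrnorm(n, mu = rep(0, 10), Sigma = sigma, empirical = TRUE)
  colnames(X) <- names(params)
  cbind(data.frame(
    call_id = sprintf("c%04d", 1:n),
    pig_id = rep(sprintf("pig%02d", 1:10), length.out = n),
    team_id = "team1", age_class = 1L, context = "x",
    valence = rep(c("negative", "positive"), length.out = n),
    stringsAsFactors = FALSE),
    as.data.frame(X), call_type = "LF")
}

test_that("PCA selection finds the factor-aligned parameter per category", {
  sel <- selectParameters(latentFeatureTable(), "LF")
  expect_setequal(sel$selected,
                  c("Dur", "AmpModRate", "Q50", "WienEntropy"))
  expect_equal(sel$retainedComponents, 1)
})

test_that("selection is deterministic and returns one per category", {
  # mutually uncorrelated parameters: eigenvalues all near 1
  set.seed(5)
  tab <- latentFeatureTable()
  for (p in c("Dur", "AmpVar", "AmpModRate", "AmpModExtent", "Q25",
              "Q50", "Q75", "FPeak", "Harmonicity", "WienEntropy"))
    tab[[p]] <- rnorm(nrow(tab))
  s1 <- selectParameters(tab, "LF")
  s2 <- selectParameters(tab, "LF")
  expect_identical(s1$selected, s2$selected)
  expect_length(s1$selected, 4)
  expect_true(s1$selected[1] == "Dur")
  expect_true(s1$selected[2] %in% c("AmpVar", "AmpModRate", "AmpModExtent"))
  expect_true(s1$selected[3] %in% c("Q25", "Q50", "Q75", "FPeak"))
  expect_true(s1$selected[4] %in% c("Harmonicity", "WienEntropy"))
  expect_true(all(abs(s1$eigenvalues - 1) < 0.6))
})

test_that("default synthetic data select Dur, AmpModRate and spectral/tonal parameters", {
  ft <- directionFixture()$features
  for (ty in c("LF", "HF")) {
    sel <- selectParameters(ft, ty)
    expect_equal(sel$selected[1], "Dur")
    expect_equal(sel$selected[2], "AmpModRate")
    expect_true(sel$selected[3] %in% c("Q25", "Q50", "Q75", "FPeak"))
    expect_true(sel$selected[4] %in% c("Harmonicity", "WienEntropy"))
  }
  expect_error(selectParameters(ft[1:3, ], "LF"), ">= 10 complete rows")
})

test_that("a constant outcome is handled degenerately", {
  tab <- latentFeatureTable(n = 60)
  tab$Dur <- 5
  res <- fitValenceLmm(tab, "Dur", "valence")
  expect_equal(unname(res$varianceComponents), c(0, 0, 0))
  expect_equal(res$pValue, 1)
  expect_equal(res$marginalR2, 0)
})

test_that("a one-sd valence shift is detected at n = 400", {
  set.seed(11)
  n <- 400
  pig <- rep(sprintf("pig%02d", 1:20), each = n / 20)
  pigEff <- rnorm(20, 0, 0.5)[rep(1:20, each = n / 20)]
  valence <- rep(c("negative", "positive"), length.out = n)
  tab <- data.frame(
    call_id = as.character(1:n), pig_id = pig,
    team_id = rep(c("team1", "team2"), each = n / 2),
    age_class = 1L, context = "x", valence = valence,
    Dur = (valence == "positive") * 1.0 + pigEff + rnorm(n),
    call_type = "LF", stringsAsFactors = FALSE)
  res <- fitValenceLmm(tab, "Dur", "valence")
  expect_lt(res$pValue, 0.001)
  expect_gt(res$coefficients[["valencepositive"]], 0)
})

test_that("null valence effects give uniform p-values (calibration)", {
  set.seed(22)
  ps <- replicate(100, {
    n <- 80
    pig <- rep(sprintf("pig%02d", 1:8), each = 10)
    pigEff <- rnorm(8, 0, 0.7)[rep(1:8, each = 10)]
    valence <- as.vector(replicate(8, sample(rep(c("negative", "positive"), 5))))
    tab <- data.frame(call_id = as.character(1:n), pig_id = pig,
                      team_id = "team1", age_class = 1L, context = "x",
                      valence = valence, Dur = pigEff + rnorm(n),
                      call_type = "LF", stringsAsFactors = FALSE)
    suppressWarnings(fitValenceLmm(tab, "Dur", "valence")$pValue)
  })
  expect_gt(mean(ps), 0.38)   # uniform mean 0.5, se ~ 0.029
  expect_lt(mean(ps), 0.62)
})

test_that("valence coefficient signs match the generating directions", {
  ft <- directionFixture()$features
  dirs <- list(LF = c(Dur = -1, AmpModRate = -1, Q50 = +1, WienEntropy = -1),
               HF = c(Dur = -1, AmpModRate = -1, Q50 = -1, WienEntropy = +1))
  for (ty in names(dirs)) {
    rows <- ft[ft$call_type == ty, ]
    for (param in names(dirs[[ty]])) {
      res <- suppressWarnings(fitValenceLmm(rows, param, "valence"))
      expect_equal(sign(res$coefficients[["valencepositive"]]),
                   unname(dirs[[ty]][param]),
                   label = paste(ty, param, "coefficient sign"))
      expect_true(res$marginalR2 >= 0 && res$marginalR2 <= 1)
    }
  }
})

test_that("marginal R2 matches its definition and degenerate cases", {
  expect_equal(marginalR2(list(fixedVariance = 0,
                               varianceComponents = c(1, 2))), 0)
  expect_equal(marginalR2(list(fixedVariance = 3,
                               varianceComponents = c(0, 0, 0))), 1)
  expect_error(marginalR2(list(fixedVariance = 0,
                               varianceComponents = c(0, 0))), "zero")
  expect_equal(marginalR2(list(fixedVariance = 1,
                               varianceComponents = c(1, 2))), 0.25)
})

test_that("marginal R2 recovers known variance shares and is affine invariant", {
  set.seed(33)
  n <- 2000
  pig <- rep(sprintf("pig%03d", 1:40), each = n / 40)
  pigEff <- rnorm(40, 0, 1)[rep(1:40, each = n / 40)]
  valence <- rep(c("negative", "positive"), length.out = n)
  # fixed variance 1 (effect +/-1), random 1, residual 2 -> R2m = 0.25
  tab <- data.frame(call_id = as.character(1:n), pig_id = pig,
                    team_id = "team1", age_class = 1L, context = "x",
                    valence = valence,
                    Dur = ifelse(valence == "positive", 1, -1) + pigEff +
                      rnorm(n, 0, sqrt(2)),
                    call_type = "LF", stringsAsFactors = FALSE)
  r1 <- suppressWarnings(fitValenceLmm(tab, "Dur", "valence"))
  expect_lt(abs(r1$marginalR2 - 0.25), 0.05)
  tab$Dur <- 3 + 2 * tab$Dur   # affine rescaling of the outcome
  r2 <- suppressWarnings(fitValenceLmm(tab, "Dur", "valence"))
  expect_equal(r1$marginalR2, r2$marginalR2, tolerance = 1e-4)
})
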