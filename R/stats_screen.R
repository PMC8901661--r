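# Parameter screening: PCA-based selection of non-redundant parameters and
# Gaussian mixed-model quantification of valence/context effects.

.paramCategories <- list(
  Duration = "Dur",
  AmplitudeModulation = c("AmpModExtent", "AmpModRate", "AmpVar"),
  Spectrum = c("FPeak", "Q25", "Q50", "Q75"),
  TonalityNoise = c("Harmonicity", "WienEntropy")
)

.allParams <- unname(unlist(.paramCategories))

#' Select four non-redundant acoustic parameters by PCA
#'
#' Standardized PCA (correlation matrix) on the complete rows of one call
#' type; components with eigenvalue > 1 are retained, and within each of
#' the four parameter categories (duration; amplitude modulation;
#' spectrum/energy distribution; tonality/noise) the parameter with the
#' largest maximum absolute loading on the retained components is
#' selected. Loadings are `rotation * sdev` (correlation-scale). Ties are
#' broken alphabetically. Rows with missing values in any parameter
#' (typically AmpModRate/AmpModExtent for unmodulated calls) are excluded
#' listwise.
#'
#' @param features feature table from [extractFeatures()].
#' @param callType "LF" or "HF"; rows are filtered on `call_type`.
#' @return list with `callType`, `loadings` (parameter x retained
#'   component), `retainedComponents`, `eigenvalues` and `selected` (4
#'   parameter names, one per category); class `PcaSelection`.
#' @export
selectParameters <- function(features, callType = c("LF", "HF")) {
  callType <- match.arg(callType)
  rows <- features[features$call_type == callType, .allParams,
                   drop = FALSE]
  rows <- rows[complete.cases(rows), , drop = FALSE]
  if (nrow(rows) < 10L)
    stop("need >= 10 complete rows of call type ", callType)
  constant <- vapply(rows, function(x) sd(x) == 0, logical(1))
  if (any(constant))
    stop("constant parameter(s): ",
         paste(names(rows)[constant], collapse = ", "))
  pca <- prcomp(rows, center = TRUE, scale. = TRUE)
  eig <- pca$sdev^2
  keep <- which(eig > 1)
  if (!length(keep)) keep <- 1L   # degenerate: retain the first component
  loadings <- pca$rotation[, keep, drop = FALSE] %*%
    diag(pca$sdev[keep], nrow = length(keep))
  colnames(loadings) <- colnames(pca$rotation)[keep]
  selected <- vapply(.paramCategories, function(params) {
    score <- apply(abs(loadings[params, , drop = FALSE]), 1L, max)
    # alphabetical tie-break: category members are stored sorted, and
    # which.max returns the first maximum
    params[which.max(score)]
  }, character(1))
  out <- list(callType = callType, loadings = loadings,
              retainedComponents = length(keep), eigenvalues = eig,
              selected = unname(selected))
  class(out) <- "PcaSelection"
  out
}

#' @export
print.PcaSelection <- function(x, ...) {
  cat(sprintf("PcaSelection (%s): %d components retained (eigenvalue > 1)\n",
              x$callType, x$retainedComponents))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a Gaussian mixed model for one acoustic parameter
#'
#' Fits `outcome ~ factor + age_class + (1 | team/pig)` by maximum
#' likelihood: the factor of interest (valence or context), age class as a
#' fixed control, and pig identity nested within recording team as random
#' intercepts. The factor's p-value is a likelihood-ratio test against the
#' model without it. Degenerate inputs (an outcome with essentially no
#' variance) are handled contractually: all variance components 0 and
#' p = 1.
#'
#' @param features feature table (typically one call type).
#' @param outcome name of the outcome parameter column.
#' @param factor `"valence"` or `"context"`.
#' @return list with `outcome`, `factor`, `coefficients` (fixed effects),
#'   `varianceComponents` (team, pig-in-team, residual), `fixedVariance`
#'   (variance of the fixed-effect predictor), `marginalR2` and `pValue`;
#'   class `LmmResult`.
#' @export
fitValenceLmm <- function(features, outcome, factor = c("valence", "context")) {
  factor <- match.arg(factor)
  stopifnot(outcome %in% names(features))
  dat <- features[, c(outcome, factor, "age_class", "team_id", "pig_id")]
  names(dat)[1L] <- ".y"
  dat <- dat[complete.cases(dat), ]
  dat$age_class <- base::factor(dat$age_class)
  dat[[factor]] <- base::factor(dat[[factor]])
  if (nlevels(dat[[factor]]) < 2L)
    stop("need >= 2 levels of ", factor)
  if (sd(dat$.y) < 1e-12 * (abs(mean(dat$.y)) + 1)) {
    res <- list(outcome = outcome, factor = factor,
                coefficients = c(`(Intercept)` = mean(dat$.y)),
                varianceComponents = c(team = 0, pig_in_team = 0,
                                       residual = 0),
                fixedVariance = 0, marginalR2 = 0, pValue = 1)
    class(res) <- "LmmResult"
    return(res)
  }
  nTeams <- length(unique(dat$team_id))
  nPigs <- length(unique(dat$pig_id))
  # degrade the random-effect structure when a grouping factor has a
  # single level: its variance component is 0 by convention
  re <- if (nTeams >= 2L && nPigs > nTeams) "(1 | team_id / pig_id)"
        else if (nPigs >= 2L) "(1 | pig_id)"
        else NULL
  if (is.null(re) || nTeams < 2L)
    warning("single team or pig: the corresponding variance component is 0")
  age <- if (nlevels(dat$age_class) > 1L) "age_class" else "1"
  fit <- function(rhs) {
    f <- paste(".y ~", rhs, if (!is.null(re)) paste("+", re))
    if (is.null(re)) stats::lm(as.formula(f), data = dat)
    else suppressMessages(suppressWarnings(lme4::lmer(
      as.formula(f), data = dat, REML = FALSE)))
  }
  full <- fit(paste(factor, "+", age))
  null <- fit(age)
  lrt <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null)))
  df <- attr(logLik(full), "df") - attr(logLik(null), "df")
  p <- pchisq(max(lrt, 0), df = max(df, 1L), lower.tail = FALSE)
  if (is(full, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(full))
    getvc <- function(nm) {
      i <- grep(nm, vc$grp)
      if (length(i)) sum(vc$vcov[i]) else 0
    }
    comps <- c(team = getvc("^team_id$"),
               pig_in_team = getvc("pig_id"),
               residual = vc$vcov[vc$grp == "Residual"])
    coefs <- lme4::fixef(full)
    fixedPart <- as.vector(model.matrix(full) %*% coefs)
  } else {
    comps <- c(team = 0, pig_in_team = 0,
               residual = summary(full)$sigma^2)
    coefs <- coef(full)
    fixedPart <- as.vector(model.matrix(full) %*% coefs)
  }
  res <- list(outcome = outcome, factor = factor,
              coefficients = coefs,
              varianceComponents = comps,
              fixedVariance = var(fixedPart),
              marginalR2 = NA_real_, pValue = p)
  res$marginalR2 <- marginalR2(res)
  class(res) <- "LmmResult"
  res
}

#' @export
print.LmmResult <- function(x, ...) {
  cat(sprintf("LmmResult: %s ~ %s | marginal R2 = %.3f, p = %.3g\n",
              x$outcome, x$factor, x$marginalR2, x$pValue))
  invisible(x)
}

#' Marginal R-squared of a mixed model
#'
#' Proportion of total variance explained by the fixed effects alone:
#' `var(fixed predictor) / (var(fixed) + sum(random components) +
#' residual)`. Returns 0 when the fixed-effect variance is 0 and 1 when
#' the random and residual components vanish while the fixed variance
#' does not.
#'
#' @param result an `LmmResult` from [fitValenceLmm()], or any list with
#'   `fixedVariance` and `varianceComponents`.
#' @return value in \[0, 1\].
#' @export
marginalR2 <- function(result) {
  vf <- result$fixedVariance
  vr <- sum(result$varianceComponents)
  if (vf < 0 || vr < 0) stop("variances must be non-negative")
  total <- vf + vr
  if (total == 0) stop("all variance components are zero")
  vf / total
}
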