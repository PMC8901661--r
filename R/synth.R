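#' Default context categories for synthetic datasets
#'
#' Nineteen context categories with a fixed valence mapping and imbalanced
#' sampling weights, emulating the breadth of situations encountered from
#' birth to slaughter (isolation dominates; surprise is rare). Weights are
#' illustrative: the per-context counts of the original recordings are not
#' public beyond a few examples, so only the imbalance structure is
#' emulated, not the exact counts.
#'
#' @return data.frame with columns `context`, `valence`, `weight`.
#' @export
defaultContexts <- function() {
  data.frame(
    context = c("isolation", "castration", "slaughterhouse", "fight",
                "restraint", "surprise", "weaning", "crushing", "hunger",
                "missed_nursing",
                "reunion", "nursing", "huddling", "positive_conditioning",
                "play", "enrichment", "free_range", "running",
                "after_nursing"),
    valence = c(rep("negative", 10), rep("positive", 9)),
    weight = c(28, 6, 5, 4, 3, 0.25, 6, 2, 3, 2,
               10, 9, 5, 2, 4, 3, 3, 2, 2.75),
    stringsAsFactors = FALSE
  )
}

# per-(call type x valence) generating distributions; directions follow the
# study conditions: positive calls shorter with fewer amplitude
# modulations in both types; spectral centre higher in positive for LF and
# lower for HF; tonality higher in positive for LF (lower Wiener entropy)
# and lower for HF.
.defaultCellParams <- function() {
  list(
    LF = list(
      negative = list(durMean = 0.45, durSd = 0.16, amRateMean = 13,
                      amRateSd = 1.3, amExtentDb = 5.5, amExtentSd = 0.3, center = 550,
                      logCenterSd = 0.05, bandHz = 200,
                      tonalRatio = 0.55, noiseFloorDb = -25, f0 = 126),
      positive = list(durMean = 0.25, durSd = 0.11, amRateMean = 6.5,
                      amRateSd = 1.3, amExtentDb = 4.5, amExtentSd = 0.3, center = 660,
                      logCenterSd = 0.05, bandHz = 200,
                      tonalRatio = 0.90, noiseFloorDb = -35, f0 = 126)
    ),
    HF = list(
      negative = list(durMean = 0.60, durSd = 0.20, amRateMean = 13,
                      amRateSd = 1.3, amExtentDb = 5.5, amExtentSd = 0.3, center = 3200,
                      logCenterSd = 0.08, bandHz = 700,
                      tonalRatio = 0.85, noiseFloorDb = -35, f0 = 700),
      positive = list(durMean = 0.40, durSd = 0.15, amRateMean = 6.5,
                      amRateSd = 1.3, amExtentDb = 4.5, amExtentSd = 0.3, center = 2800,
                      logCenterSd = 0.08, bandHz = 700,
                      tonalRatio = 0.45, noiseFloorDb = -25, f0 = 700)
    )
  )
}

#' Specification of a synthetic pig-call dataset
#'
#' Defines the generating conditions for [synthesizeDataset()]: pigs nested
#' in recording teams, three age classes, 19 context categories with a
#' fixed valence mapping and imbalanced weights, and per-(call type x
#' valence) parameter distributions (duration, amplitude-modulation rate
#' and extent, target spectral centre, tonal-to-noise energy ratio).
#' Per-pig random offsets on log-duration and log-centre-frequency induce
#' the individual-identity structure that the pDFA's control factor and the
#' mixed models' random effects are designed to absorb. The pig roster
#' (with ages and offsets) is drawn deterministically from `rngSeed` at
#' construction time, so a spec is a complete, reproducible description of
#' the generating process.
#'
#' @param nPigs number of pigs.
#' @param nTeams number of recording teams pigs are allocated to.
#' @param ageClassProbs length-3 probabilities of age classes
#'   (1 = 1-25 d, 2 = 32-43 d, 3 = >= 85 d); must sum to 1.
#' @param contexts data.frame as from [defaultContexts()].
#' @param cellParams nested list `type$valence` of generating
#'   distributions; see [defaultContexts()] and the package vignette.
#' @param lfProb named probabilities that a negative/positive call is LF.
#' @param pigLogDurSd,pigLogCenterSd per-pig random offset SDs on the log
#'   scale.
#' @param sampleRate waveform sampling rate, Hz.
#' @param rngSeed integer seed governing the pig roster and, through
#'   [synthesizeDataset()], the whole dataset.
#' @return object of class `SynthSpec` (a validated list).
#' @examples
#' spec <- synthSpec(nPigs = 8, rngSeed = 42)
#' @export
synthSpec <- function(nPigs = 24, nTeams = 4,
                      ageClassProbs = c(0.4, 0.3, 0.3),
                      contexts = defaultContexts(),
                      cellParams = .defaultCellParams(),
                      lfProb = c(negative = 0.67, positive = 0.90),
                      pigLogDurSd = 0.15, pigLogCenterSd = 0.05,
                      sampleRate = 44100, rngSeed = 1L) {
  stopifnot(abs(sum(ageClassProbs) - 1) < 1e-8, all(ageClassProbs >= 0),
            nPigs >= 1, nTeams >= 1,
            all(c("context", "valence", "weight") %in% names(contexts)),
            !anyDuplicated(contexts$context),
            all(contexts$valence %in% c("negative", "positive")),
            pigLogDurSd >= 0, pigLogCenterSd >= 0)
  for (ty in c("LF", "HF")) for (va in c("negative", "positive")) {
    p <- cellParams[[ty]][[va]]
    stopifnot(p$durSd >= 0, p$amRateSd >= 0, p$durMean > 0,
              p$amRateMean > 0, p$tonalRatio >= 0, p$tonalRatio <= 1)
    # all synthesized energy must stay below Nyquist
    if (sampleRate < 2 * (p$center * exp(4 * p$logCenterSd) + 3 * p$bandHz))
      stop("sampleRate too low for cell spectral centre ", p$center, " Hz")
  }
  # deterministic pig roster: team allocation, age, per-pig offsets
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(rngSeed)
  ageClass <- sample.int(3L, nPigs, replace = TRUE, prob = ageClassProbs)
  ageDays <- vapply(ageClass, function(cl)
    switch(cl, sample(1:25, 1), sample(32:43, 1), sample(85:200, 1)),
    numeric(1))
  pigs <- data.frame(
    pig_id = sprintf("pig%03d", seq_len(nPigs)),
    team_id = sprintf("team%d", rep_len(seq_len(nTeams), nPigs)),
    age_days = ageDays,
    age_class = as.integer(ageClass),
    log_dur_offset = rnorm(nPigs, 0, pigLogDurSd),
    log_center_offset = rnorm(nPigs, 0, pigLogCenterSd),
    stringsAsFactors = FALSE
  )
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  spec <- list(nPigs = nPigs, nTeams = nTeams,
               ageClassProbs = ageClassProbs, contexts = contexts,
               cellParams = cellParams, lfProb = lfProb,
               pigLogDurSd = pigLogDurSd, pigLogCenterSd = pigLogCenterSd,
               sampleRate = sampleRate, rngSeed = as.integer(rngSeed),
               pigs = pigs)
  class(spec) <- "SynthSpec"
  spec
}

#' @export
print.SynthSpec <- function(x, ...) {
  cat(sprintf(
    "SynthSpec: %d pigs in %d teams, %d contexts, %g Hz, seed %d\n",
    x$nPigs, x$nTeams, nrow(x$contexts), x$sampleRate, x$rngSeed))
  invisible(x)
}

# truncated-positive draw with bounded retries
.drawPositive <- function(mean, sd, lower = 0, tries = 20L) {
  for (i in seq_len(tries)) {
    v <- rnorm(1, mean, sd)
    if (v > lower) return(v)
  }
  stop("could not draw a positive value for mean ", mean, ", sd ", sd)
}

# Hermitian-symmetric inverse FFT of a one-sided complex spectrum (bins
# 2..n/2 given; DC and Nyquist zero); returns a real signal of length n.
.synthFromSpectrum <- function(spec_half, n) {
  X <- complex(n)
  nh <- length(spec_half)
  X[2:(nh + 1)] <- spec_half
  X[n:(n - nh + 1)] <- Conj(spec_half)
  Re(fft(X, inverse = TRUE)) / n
}

#' Synthesize one call
#'
#' Generates a single call waveform as an additive harmonic stack
#' (fundamental plus partials, amplitudes shaped by a Gaussian envelope on
#' log-frequency centred at the drawn spectral centre) mixed with
#' band-shaped Gaussian noise at the drawn tonal-to-noise energy ratio,
#' multiplied by an attack/decay envelope and a sinusoidal
#' amplitude-modulation envelope `1 + m sin(2 pi f t)`, with `m` chosen so
#' that the peak-to-trough intensity excursion equals the drawn AM extent
#' in dB. Draws come from the `spec` cell distributions plus the pig's
#' random offsets; non-positive draws are re-drawn a bounded number of
#' times.
#'
#' @param spec a [synthSpec()] object.
#' @param callType "LF" or "HF".
#' @param valence "negative" or "positive".
#' @param pigId a pig registered in `spec$pigs`.
#' @param context context label (defaults to a draw from the contexts of
#'   the requested valence).
#' @param callId identifier for the new call.
#' @param seed optional integer; if given, the RNG is seeded so the call is
#'   exactly reproducible.
#' @return a [CallRecording-class] with `synthParams` holding the draws.
#' @export
synthesizeCall <- function(spec, callType, valence, pigId,
                           context = NULL, callId = "call", seed = NULL) {
  stopifnot(inherits(spec, "SynthSpec"))
  if (!callType %in% c("LF", "HF")) stop("invalid callType: ", callType)
  if (!valence %in% c("negative", "positive"))
    stop("invalid valence: ", valence)
  row <- match(pigId, spec$pigs$pig_id)
  if (is.na(row)) stop("pig not registered in spec: ", pigId)
  if (!is.null(seed)) set.seed(seed)
  pig <- spec$pigs[row, ]
  p <- spec$cellParams[[callType]][[valence]]
  sr <- spec$sampleRate
  if (is.null(context)) {
    ctx <- spec$contexts[spec$contexts$valence == valence, ]
    context <- sample(ctx$context, 1, prob = ctx$weight)
  } else {
    map <- spec$contexts$valence[match(context, spec$contexts$context)]
    if (is.na(map) || map != valence)
      stop("context ", context, " does not map to valence ", valence)
  }

  # calls shorter than ~50 ms cannot carry the analysis frames; truncate
  dur <- .drawPositive(p$durMean * exp(pig$log_dur_offset), p$durSd,
                       lower = 0.05)
  amRate <- .drawPositive(p$amRateMean, p$amRateSd, lower = 0.5)
  extentSd <- if (is.null(p$amExtentSd)) 0 else p$amExtentSd
  amExtent <- .drawPositive(p$amExtentDb, extentSd, lower = 1)
  center <- p$center * exp(pig$log_center_offset +
                             rnorm(1, 0, p$logCenterSd))
  n <- max(round(dur * sr), 16L)
  # synthesize on a power-of-two grid (fast FFT) and keep the first n
  # samples; frequency quantization is sr/nf < 2 Hz for typical calls
  nf <- nextn(n, 2)
  nh <- nf %/% 2L - 1L
  f <- seq_len(nh) * sr / nf
  # Gaussian band of constant width in Hz so that valence shifts of the
  # centre do not change the number of occupied bins (Wiener entropy must
  # respond to the tonal ratio, not to the band placement)
  # the broadband floor sets the call's spectral flatness (Wiener
  # entropy): a higher floor means a noisier, flatter spectrum
  shape <- pmax(exp(-(f - center)^2 / (2 * p$bandHz^2)),
                10^(p$noiseFloorDb / 20))

  # harmonic stack: exact bin multiples so partials stay harmonically
  # related on the synthesis grid
  bin0 <- max(round(p$f0 * nf / sr), 1L)
  bins <- seq.int(bin0, nh, by = bin0)
  amp <- exp(-(f[bins] - center)^2 / (2 * p$bandHz^2))
  harmSpec <- complex(nh)
  harmSpec[bins] <- amp * exp(1i * runif(length(bins), 0, 2 * pi))
  harm <- .synthFromSpectrum(harmSpec, nf)[seq_len(n)]

  noiseSpec <- shape * (rnorm(nh) + 1i * rnorm(nh)) / sqrt(2)
  noise <- .synthFromSpectrum(noiseSpec, nf)[seq_len(n)]

  rmsH <- sqrt(mean(harm^2)); rmsN <- sqrt(mean(noise^2))
  if (rmsH > 0) harm <- harm / rmsH
  if (rmsN > 0) noise <- noise / rmsN
  x <- sqrt(p$tonalRatio) * harm + sqrt(1 - p$tonalRatio) * noise

  # flatten the intrinsic envelope (stochastic noise beating) so the
  # intensity contour carries only the imposed AM and fades; without this
  # the envelope ripple of band-limited noise adds spurious AM cycles
  # a 2 ms window tracks (and removes) both slow noise fading and partial
  # beating down to ~500 Hz while leaving the carrier itself intact; the
  # imposed AM below is applied afterwards, so the intensity contour of
  # the finished call carries the drawn modulation and little else
  for (w in c(0.002, 0.002, 0.002, 0.010, 0.010)) {
    env <- sqrt(.movMeanSq(x, max(round(w * sr), 2L)))
    # lowpass the envelope estimate so dividing by it cannot inject
    # carrier-rate wobble into the signal
    env <- .movMean(env, max(round(w * sr), 2L))
    env <- pmax(env, 0.05 * stats::median(env))
    x <- x / env
  }

  t <- (seq_len(n) - 1L) / sr
  m <- (10^(amExtent / 20) - 1) / (10^(amExtent / 20) + 1)
  am <- 1 + m * sin(2 * pi * amRate * t - pi / 2)
  # micro-roughness: a fixed-depth wobble at a random 30-90 Hz frequency,
  # well under the 2 dB cycle-detection prominence; the frequency draw
  # varies the cumulative amplitude variation between calls while leaving
  # cycle counts and (near-constant) measured AM depth alone
  aR <- runif(1, 0.2, 0.9)
  mR <- (10^(aR / 20) - 1) / (10^(aR / 20) + 1)
  am <- am * (1 + mR * sin(2 * pi * runif(1, 35, 60) * t +
                             runif(1, 0, 2 * pi)))
  # short fades: cropped calls start and end near-abruptly, and long
  # fades would turn the cumulative amplitude variation into a proxy for
  # 1/duration
  fadeN <- max(min(round(0.05 * n), round(0.002 * sr)), 2L)
  fade <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(fadeN) / fadeN))
  fade[seq_len(fadeN)] <- ramp
  fade[n - seq_len(fadeN) + 1L] <- ramp
  x <- x * am * fade
  x <- 0.9 * x / max(abs(x))

  new("CallRecording",
      callId = callId, waveform = x, sampleRate = sr,
      pigId = pig$pig_id, teamId = pig$team_id,
      ageDays = pig$age_days, ageClass = pig$age_class,
      context = context, valence = valence,
      synthParams = list(callType = callType, dur = n / sr,
                         durDrawn = dur, amRate = amRate,
                         amExtentDb = amExtent, center = center,
                         tonalRatio = p$tonalRatio, f0 = p$f0))
}

#' Synthesize a labelled dataset of calls
#'
#' Draws a whole dataset under `spec`: contexts are sampled with their
#' (imbalanced) weights, each call's valence is its context's mapped
#' valence, the call type is drawn with the valence-dependent LF
#' probability, and each call is synthesized with [synthesizeCall()]. With
#' `nPerCell` the dataset is instead balanced by design cell (call type x
#' valence), which is what the direction-recovery analyses use.
#'
#' @param spec a [synthSpec()] object.
#' @param nCalls total number of calls (ignored when `nPerCell` is given).
#' @param nPerCell optional count per (LF/HF x negative/positive) cell.
#' @return a [CallSet-class]; `callData` gains columns `true_call_type`
#'   and the generating draws columns `true_dur`, `true_am_rate`.
#' @export
synthesizeDataset <- function(spec, nCalls = 500, nPerCell = NULL) {
  stopifnot(inherits(spec, "SynthSpec"))
  set.seed(spec$rngSeed)
  if (is.null(nPerCell)) {
    if (nCalls < 1) stop("at least one call must be requested")
    ctxIdx <- sample.int(nrow(spec$contexts), nCalls, replace = TRUE,
                         prob = spec$contexts$weight)
    valence <- spec$contexts$valence[ctxIdx]
    context <- spec$contexts$context[ctxIdx]
    callType <- ifelse(runif(nCalls) < spec$lfProb[valence], "LF", "HF")
  } else {
    if (nPerCell < 1) stop("at least one call per cell must be requested")
    cells <- expand.grid(callType = c("LF", "HF"),
                         valence = c("negative", "positive"),
                         stringsAsFactors = FALSE)
    callType <- rep(cells$callType, each = nPerCell)
    valence <- rep(cells$valence, each = nPerCell)
    context <- vapply(valence, function(v) {
      ctx <- spec$contexts[spec$contexts$valence == v, ]
      sample(ctx$context, 1, prob = ctx$weight)
    }, character(1))
    nCalls <- length(callType)
  }
  pigIdx <- sample.int(spec$nPigs, nCalls, replace = TRUE)
  calls <- vector("list", nCalls)
  for (i in seq_len(nCalls)) {
    calls[[i]] <- synthesizeCall(
      spec, callType[i], valence[i], spec$pigs$pig_id[pigIdx[i]],
      context = context[i], callId = sprintf("call%05d", i))
  }
  md <- data.frame(
    call_id = vapply(calls, function(x) x@callId, character(1)),
    pig_id = spec$pigs$pig_id[pigIdx],
    team_id = spec$pigs$team_id[pigIdx],
    age_days = spec$pigs$age_days[pigIdx],
    age_class = spec$pigs$age_class[pigIdx],
    context = context,
    valence = valence,
    true_call_type = callType,
    true_dur = vapply(calls, function(x) x@synthParams$dur, numeric(1)),
    true_am_rate = vapply(calls, function(x) x@synthParams$amRate,
                          numeric(1)),
    stringsAsFactors = FALSE
  )
  new("CallSet", calls = calls, callData = md)
}
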