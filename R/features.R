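#' Duration of a cropped call
#'
#' @param call a [CallRecording-class] (pre-cropped to the call).
#' @return duration in seconds (`n_samples / sample_rate`).
#' @export
callDuration <- function(call) {
  stopifnot(is(call, "CallRecording"))
  if (length(call@waveform) == 0L) stop("empty waveform")
  length(call@waveform) / call@sampleRate
}

#' Intensity contour of a call
#'
#' Per-frame RMS level in dB relative to full scale, on frames of
#' `frameLen` seconds advanced by `frameStep` seconds and spanning the
#' call. Silent frames are floored at `floorDb` rather than -Inf. The
#' defaults (10 ms frames, 1 ms step) resolve amplitude modulation up to
#' about 50 Hz.
#'
#' @param call a [CallRecording-class].
#' @param frameLen,frameStep frame length and hop, seconds.
#' @param floorDb level floor, dB re full scale.
#' @return list with `times` (frame centres, s), `levels` (dB) and
#'   `frameStep` (s); class `IntensityContour`.
#' @export
intensityContour <- function(call, frameLen = 0.010, frameStep = 0.001,
                             floorDb = -70) {
  stopifnot(is(call, "CallRecording"))
  x <- call@waveform
  sr <- call@sampleRate
  wl <- max(round(frameLen * sr), 2L)
  hop <- max(round(frameStep * sr), 1L)
  if (length(x) < wl) stop("call shorter than one frame")
  starts <- seq(1L, length(x) - wl + 1L, by = hop)
  # O(n) frame energies from a cumulative sum of squares
  cs <- c(0, cumsum(x^2))
  energy <- cs[starts + wl] - cs[starts]
  levels <- .ampToDb(sqrt(energy / wl), floorDb)
  out <- list(times = (starts - 1L + wl / 2) / sr, levels = levels,
              frameStep = hop / sr)
  class(out) <- "IntensityContour"
  out
}

#' Amplitude features from an intensity contour
#'
#' Computes the three amplitude-modulation parameters. `AmpVar` is the
#' cumulative absolute variation of the contour divided by call duration
#' (dB/s). Modulation cycles are alternating prominent trough/peak/trough
#' sequences (prominence threshold `prominenceDb`, default 2 dB to
#' suppress micro-ripple); `AmpModRate` is the number of complete cycles
#' per second and `AmpModExtent` the mean peak-to-adjacent-trough depth in
#' dB. When no complete cycle exists both modulation values are `NA`, as
#' happens for short flat calls.
#'
#' @param contour an `IntensityContour` (or a bare numeric vector of dB
#'   levels).
#' @param dur call duration, seconds.
#' @param prominenceDb minimum dB excursion for a reversal to count.
#' @return named list `AmpVar`, `AmpModRate`, `AmpModExtent`.
#' @export
amplitudeFeatures <- function(contour, dur, prominenceDb = 2) {
  levels <- if (inherits(contour, "IntensityContour")) contour$levels
            else as.numeric(contour)
  if (length(levels) < 2L) stop("at least 2 contour frames are required")
  stopifnot(dur > 0)
  ampVar <- sum(abs(diff(levels))) / dur
  tp <- .turningPoints(levels, prominenceDb)
  ampModRate <- NA_real_
  ampModExtent <- NA_real_
  if (nrow(tp) >= 3L) {
    # complete cycles: peaks flanked by troughs on both sides
    peaks <- which(tp$type == "peak")
    peaks <- peaks[peaks > 1L & peaks < nrow(tp)]
    if (length(peaks)) {
      depth <- vapply(peaks, function(j) {
        pk <- levels[tp$idx[j]]
        pk - mean(c(levels[tp$idx[j - 1L]], levels[tp$idx[j + 1L]]))
      }, numeric(1))
      ampModRate <- length(peaks) / dur
      ampModExtent <- mean(depth)
    }
  }
  list(AmpVar = ampVar, AmpModRate = ampModRate,
       AmpModExtent = ampModExtent)
}

#' Average power spectrum of a call
#'
#' Mean of per-frame power spectra (Hann-windowed frames, 50% overlap);
#' calls shorter than one frame fall back to a single whole-call spectrum.
#'
#' @param call a [CallRecording-class].
#' @param nFft FFT length (and frame length), samples.
#' @return list with `freqs` (Hz, 0..Nyquist) and `power` (linear power
#'   per bin); class `AverageSpectrum`.
#' @export
averageSpectrum <- function(call, nFft = 1024) {
  stopifnot(is(call, "CallRecording"))
  x <- call@waveform
  if (all(x == 0)) stop("all-zero waveform has no spectrum")
  sr <- call@sampleRate
  n <- length(x)
  if (n < nFft) {
    nf <- nextn(n, 2)
    X <- fft(c(x * .hann(n), rep(0, nf - n)))
    pw <- Mod(X[seq_len(nf / 2 + 1)])^2
    freqs <- (0:(nf / 2)) * sr / nf
  } else {
    hop <- nFft %/% 2L
    starts <- seq(1L, n - nFft + 1L, by = hop)
    frames <- matrix(x[outer(0:(nFft - 1L), starts, "+")], nrow = nFft)
    frames <- frames * .hann(nFft)
    X <- mvfft(frames)
    pw <- rowMeans(Mod(X[seq_len(nFft / 2 + 1L), , drop = FALSE])^2)
    freqs <- (0:(nFft / 2)) * sr / nFft
  }
  out <- list(freqs = freqs, power = pw)
  class(out) <- "AverageSpectrum"
  out
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Spectral energy-distribution features
#'
#' Energy quartiles, peak frequency and Wiener entropy of a power
#' spectrum. `Qx` is the smallest frequency at which the cumulative power
#' reaches x% of the total (Q50 is the spectral centre of gravity used for
#' LF/HF call typing). Wiener entropy is the natural log of the ratio of
#' the geometric to the arithmetic mean of the power bins, in (-Inf, 0]:
#' 0 for a perfectly flat (noisy) spectrum, increasingly negative for
#' tonal ones. Power bins are floored at `floorRatio` times the maximum
#' bin so the log stays finite.
#'
#' @param spec an `AverageSpectrum` (or `list(freqs, power)`).
#' @param floorRatio relative power floor for the entropy computation.
#' @return named list `Q25`, `Q50`, `Q75`, `FPeak` (Hz), `WienEntropy`.
#' @export
spectralFeatures <- function(spec, floorRatio = 1e-10) {
  freqs <- spec$freqs; power <- spec$power
  stopifnot(length(freqs) == length(power), all(power >= 0))
  total <- sum(power)
  if (total <= 0) stop("zero total power")
  cum <- cumsum(power) / total
  qAt <- function(q) freqs[which(cum >= q)[1L]]
  pw <- pmax(power, max(power) * floorRatio)
  wien <- mean(log(pw)) - log(mean(pw))
  list(Q25 = qAt(0.25), Q50 = qAt(0.50), Q75 = qAt(0.75),
       FPeak = freqs[which.max(power)], WienEntropy = min(wien, 0))
}

#' Harmonic-to-noise ratio of a call
#'
#' Degree of acoustic periodicity: the maximum normalized autocorrelation
#' `r` over lags corresponding to fundamental frequencies between
#' `pitchFloor` and `pitchCeiling` is converted to
#' `HNR = 10 log10(r / (1 - r))` dB and clamped to `clamp`. Higher values
#' indicate more tonal calls. The default lag range (60-2000 Hz) spans
#' grunt to squeal fundamentals.
#'
#' @param call a [CallRecording-class].
#' @param pitchFloor,pitchCeiling candidate fundamental range, Hz.
#' @param clamp length-2 dB clamp.
#' @return HNR in dB.
#' @export
harmonicity <- function(call, pitchFloor = 60, pitchCeiling = 2000,
                        clamp = c(-10, 40)) {
  stopifnot(is(call, "CallRecording"), pitchFloor < pitchCeiling)
  x <- call@waveform
  sr <- call@sampleRate
  if (length(x) < 2 * sr / pitchFloor)
    stop("call too short for pitch floor ", pitchFloor, " Hz")
  x <- x - mean(x)
  n <- length(x)
  nf <- nextn(2L * n, 2)
  # autocorrelation via FFT
  X <- fft(c(x, rep(0, nf - n)))
  ac <- Re(fft(Mod(X)^2, inverse = TRUE))[seq_len(n)] / nf
  if (ac[1] <= 0) return(clamp[1])
  # unbiased estimate: lag k sums over n - k products only
  ac <- ac / ac[1] * n / (n - seq_len(n) + 1)
  lagMin <- max(floor(sr / pitchCeiling), 1L)
  lagMax <- min(ceiling(sr / pitchFloor), n - 1L)
  r <- max(ac[(lagMin + 1L):(lagMax + 1L)])
  r <- min(max(r, 1e-12), 1 - 1e-12)
  hnr <- 10 * log10(r / (1 - r))
  min(max(hnr, clamp[1]), clamp[2])
}

#' Age-specific LF/HF call typing cutoffs (Hz)
#'
#' Spectral centre-of-gravity cutoffs separating low-frequency from
#' high-frequency calls: 2414 Hz for age class 1 (1-25 d), 2153 Hz for
#' age class 2 (32-43 d) and 896 Hz for age class 3 (>= 85 d).
#'
#' @return named numeric vector of length 3.
#' @export
callTypeCutoffs <- function() c(`1` = 2414, `2` = 2153, `3` = 896)

#' Classify a call as LF or HF from its spectral centre of gravity
#'
#' A call is HF when its Q50 exceeds the age-class cutoff, LF otherwise
#' (a Q50 exactly at the cutoff is LF).
#'
#' @param q50 spectral centre of gravity, Hz.
#' @param ageClass integer 1, 2 or 3.
#' @return "LF" or "HF" (vectorized).
#' @export
classifyCallType <- function(q50, ageClass) {
  stopifnot(all(q50 > 0))
  if (!all(ageClass %in% 1:3)) stop("unknown age class")
  cut <- callTypeCutoffs()[as.character(ageClass)]
  unname(ifelse(q50 > cut, "HF", "LF"))
}

#' Extract the full acoustic feature table from a CallSet
#'
#' Computes, for every call, the ten acoustic parameters — Dur (s), AmpVar
#' (dB/s), AmpModRate (1/s), AmpModExtent (dB), Q25/Q50/Q75/FPeak (Hz),
#' Harmonicity (dB) and WienEntropy — plus the LF/HF call type assigned
#' from Q50 and the pig's age class. AmpModRate and AmpModExtent are `NA`
#' for calls without a complete modulation cycle.
#'
#' @param x a [CallSet-class].
#' @param frameLen,frameStep,floorDb intensity-contour settings, see
#'   [intensityContour()].
#' @param prominenceDb AM cycle prominence, see [amplitudeFeatures()].
#' @param nFft spectrum frame length, see [averageSpectrum()].
#' @return data.frame with the call metadata columns followed by the ten
#'   parameters and `call_type`.
#' @export
extractFeatures <- function(x, frameLen = 0.010, frameStep = 0.001,
                            floorDb = -70, prominenceDb = 2,
                            nFft = 1024) {
  stopifnot(is(x, "CallSet"))
  rows <- lapply(x@calls, function(call) {
    dur <- callDuration(call)
    ic <- intensityContour(call, frameLen, frameStep, floorDb)
    af <- amplitudeFeatures(ic, dur, prominenceDb)
    sf <- spectralFeatures(averageSpectrum(call, nFft))
    data.frame(
      Dur = dur, AmpVar = af$AmpVar, AmpModRate = af$AmpModRate,
      AmpModExtent = af$AmpModExtent, Q25 = sf$Q25, Q50 = sf$Q50,
      Q75 = sf$Q75, FPeak = sf$FPeak,
      Harmonicity = harmonicity(call),
      WienEntropy = sf$WienEntropy)
  })
  feats <- do.call(rbind, rows)
  out <- cbind(x@callData, feats)
  out$call_type <- classifyCallType(out$Q50, out$age_class)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table CSV
#'
#' Column layout: call_id, pig_id, team_id, age_class, context, valence,
#' the ten acoustic parameters, call_type; missing values are written as
#' empty fields.
#'
#' @param features data.frame from [extractFeatures()].
#' @param path CSV path.
#' @export
writeFeatures <- function(features, path) {
  cols <- c("call_id", "pig_id", "team_id", "age_class", "context",
            "valence", "Dur", "AmpVar", "AmpModRate", "AmpModExtent",
            "Q25", "Q50", "Q75", "FPeak", "Harmonicity", "WienEntropy",
            "call_type")
  write.csv(features[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) read.csv(path, stringsAsFactors = FALSE)
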