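#' Spectrogram settings for the image classifier
#'
#' Fixed-size log-magnitude spectrograms: every call is centrally
#' zero-padded to `padTarget` seconds (the duration of the longest
#' recording the recipe was designed around, 3.595 s), analyzed with a
#' 3 ms window and a 512-point DFT, and resized to the network input
#' resolution. `overlap` defaults to 0.99 (hop = 1% of the window, at
#' least one sample); smaller values trade time resolution for speed.
#'
#' @param padTarget pad length, seconds.
#' @param windowS analysis window, seconds.
#' @param overlap fractional window overlap in \[0, 1).
#' @param nFft DFT length, samples.
#' @param resolution c(rows, cols) of the output image.
#' @param floorDb dynamic-range floor below the image maximum, dB.
#' @return list of class `SpectrogramConfig`.
#' @export
spectrogramConfig <- function(padTarget = 3.595, windowS = 0.003,
                              overlap = 0.99, nFft = 512,
                              resolution = c(64, 64), floorDb = -80) {
  stopifnot(padTarget > 0, windowS > 0, overlap >= 0, overlap < 1,
            nFft >= 8, length(resolution) == 2L, floorDb < 0)
  out <- list(padTarget = padTarget, windowS = windowS, overlap = overlap,
              nFft = as.integer(nFft), resolution = as.integer(resolution),
              floorDb = floorDb)
  class(out) <- "SpectrogramConfig"
  out
}

#' Centrally zero-pad a waveform to a target duration
#'
#' Pads with `floor(extra / 2)` zeros on the left and the remainder on
#' the right, so the call sits centrally within `padTarget` seconds (left
#' and right pads differ by at most one sample).
#'
#' @param x numeric waveform.
#' @param sampleRate Hz.
#' @param padTarget seconds.
#' @return list with `samples`, `padLeft` and `padRight` (sample counts).
#' @export
padWaveform <- function(x, sampleRate, padTarget) {
  target <- round(padTarget * sampleRate)
  if (length(x) > target)
    stop("call longer than the pad target (", padTarget, " s)")
  extra <- target - length(x)
  left <- extra %/% 2L
  right <- extra - left
  list(samples = c(rep(0, left), x, rep(0, right)),
       padLeft = left, padRight = right)
}

#' Compute the fixed-size log-magnitude spectrogram of a call
#'
#' @param call a [CallRecording-class] (duration must not exceed the pad
#'   target).
#' @param cfg a [spectrogramConfig()].
#' @return list of class `Spectrogram` with `image` (resolution\[1\] x
#'   resolution\[2\], dB, frequency increasing with row), `freqs` and
#'   `times` of the underlying STFT grid, `padLeft` (s) and `padTarget`.
#' @export
makeSpectrogram <- function(call, cfg = spectrogramConfig()) {
  stopifnot(is(call, "CallRecording"), inherits(cfg, "SpectrogramConfig"))
  sr <- call@sampleRate
  padded <- padWaveform(call@waveform, sr, cfg$padTarget)
  wl <- max(round(cfg$windowS * sr), 4L)
  if (wl > cfg$nFft)
    stop("window (", wl, " samples) longer than the DFT length")
  hop <- max(1L, round((1 - cfg$overlap) * wl))
  sg <- signal::specgram(padded$samples, n = cfg$nFft, Fs = sr,
                         window = signal::hanning(wl),
                         overlap = wl - hop)
  mag <- Mod(sg$S)
  top <- max(mag)
  if (top <= 0) {
    img <- matrix(cfg$floorDb, nrow(mag), ncol(mag))
  } else {
    img <- 20 * log10(pmax(mag, top * 10^(cfg$floorDb / 20)))
  }
  out <- list(image = .resizeBilinear(img, cfg$resolution),
              freqs = as.numeric(sg$f), times = as.numeric(sg$t),
              padLeft = padded$padLeft / sr, padTarget = cfg$padTarget)
  class(out) <- "Spectrogram"
  out
}

#' Stack spectrogram images of a CallSet into a tensor
#'
#' Computes one spectrogram per call and returns an (rows x cols x n)
#' array of per-image standardized (zero mean, unit variance) pixels,
#' the input format of [trainClassifier()].
#'
#' @param x a [CallSet-class] (or list of CallRecording).
#' @param cfg a [spectrogramConfig()].
#' @return numeric array (rows, cols, n).
#' @export
spectrogramTensor <- function(x, cfg = spectrogramConfig()) {
  calls <- if (is(x, "CallSet")) x@calls else x
  imgs <- lapply(calls, function(cl) {
    im <- makeSpectrogram(cl, cfg)$image
    s <- sd(im)
    if (s == 0) im * 0 else (im - mean(im)) / s
  })
  array(unlist(imgs, use.names = FALSE),
        dim = c(cfg$resolution[1L], cfg$resolution[2L], length(imgs)))
}
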