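# Shared fixtures, built lazily once per test session.

.fixtures <- new.env(parent = emptyenv())

# deterministic single-call construction for feature-operator tests
makeCall <- function(waveform, sampleRate = 16000, ageClass = 1L) {
  ageDays <- c(20, 40, 100)[ageClass]
  new("CallRecording", callId = "test", waveform = waveform,
      sampleRate = sampleRate, pigId = "pig001", teamId = "team1",
      ageDays = ageDays, ageClass = as.integer(ageClass),
      context = "isolation", valence = "negative")
}

toneCall <- function(freq, dur = 1, sampleRate = 16000, amRate = NULL,
                     amDepth = 0.5) {
  t <- seq(0, dur - 1 / sampleRate, by = 1 / sampleRate)
  x <- sin(2 * pi * freq * t)
  if (!is.null(amRate)) x <- x * (1 + amDepth * sin(2 * pi * amRate * t))
  makeCall(0.9 * x / max(abs(x)), sampleRate)
}

# the default-condition dataset used by the direction suite and the
# screening tests: 200 calls per (call type x valence) cell
directionFixture <- function() {
  if (is.null(.fixtures$direction)) {
    spec <- synthSpec(nPigs = 16, rngSeed = 101L)
    calls <- synthesizeDataset(spec, nPerCell = 200)
    .fixtures$direction <- list(spec = spec, calls = calls,
                                features = extractFeatures(calls))
  }
  .fixtures$direction
}

# a small trained classifier on a two-band synthetic task, shared by the
# classifier and embedding tests
cnnFixture <- function() {
  if (is.null(.fixtures$cnn)) {
    spec <- synthSpec(nPigs = 8, sampleRate = 16000, rngSeed = 5L)
    calls <- synthesizeDataset(spec, nPerCell = 40)
    cfg <- spectrogramConfig(overlap = 0.5, resolution = c(32, 32))
    images <- spectrogramTensor(calls, cfg)
    labels <- callData(calls)$true_call_type  # disjoint spectral bands
    fit <- trainClassifier(
      images, labels,
      trainConfig("valence", epochs = 6, nTrials = 1, rngSeed = 2L))
    # second network trained on the (band-independent) valence labels,
    # used by the embedding comparisons
    valenceFit <- trainClassifier(
      images, callData(calls)$valence,
      trainConfig("valence", epochs = 25, nTrials = 1, rngSeed = 12L))
    .fixtures$cnn <- list(calls = calls, cfg = cfg, images = images,
                          labels = labels, fit = fit,
                          valenceFit = valenceFit)
  }
  .fixtures$cnn
}

# null feature tables for pDFA calibration: labels balanced within pig
# and independent of the four features
nullPdfaFeatures <- function(seed, nPigs = 10, callsPerPig = 20) {
  set.seed(seed)
  n <- nPigs * callsPerPig
  data.frame(
    call_id = sprintf("c%04d", seq_len(n)),
    pig_id = rep(sprintf("pig%02d", seq_len(nPigs)), each = callsPerPig),
    team_id = "team1", age_class = 1L, context = "x",
    valence = as.vector(replicate(nPigs,
      sample(rep(c("negative", "positive"), callsPerPig / 2)))),
    Dur = rnorm(n), AmpModRate = rnorm(n), Q50 = rnorm(n),
    WienEntropy = rnorm(n),
    call_type = "LF", stringsAsFactors = FALSE)
}
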