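test_that("duration is samples over sample rate", {
  expect_equal(callDuration(makeCall(numeric(22050) + 0.1, 44100)), 0.5)
  expect_equal(callDuration(makeCall(0.5, 44100)), 1 / 44100)
  # synthesizer contract: a 0.8 s request comes back within one sample
  spec <- synthSpec(nPigs = 2, rngSeed = 8L, pigLogDurSd = 0)
  spec$cellParams$LF$negative$durMean <- 0.8
  spec$cellParams$LF$negative$durSd <- 0
  cl <- synthesizeCall(spec, "LF", "negative", "pig001", seed = 1L)
  expect_lte(abs(callDuration(cl) - 0.8), 1 / sampleRate(cl))
})

test_that("intensity contour is flat for steady tones and floored for silence", {
  ic <- intensityContour(toneCall(440, dur = 0.5))
  mid <- ic$levels[20:(length(ic$levels) - 20)]
  expect_lt(diff(range(mid)), 0.5)
  icSil <- intensityContour(makeCall(numeric(8000), 16000))
  expect_true(all(is.finite(icSil$levels)))
  expect_true(all(icSil$levels == -70))
  expect_error(intensityContour(makeCall(rep(0.1, 10), 16000)),
               "shorter than one frame")
  # 10 Hz AM appears as a 10 Hz contour oscillation (FFT oracle)
  ic10 <- intensityContour(toneCall(1000, dur = 1, amRate = 10))
  lev <- ic10$levels - mean(ic10$levels)
  sp <- Mod(fft(lev))[2:(length(lev) %/% 2)]
  fAxis <- seq_along(sp) / (length(lev) * ic10$frameStep)
  expect_lt(abs(fAxis[which.max(sp)] - 10), 1)
})

test_that("amplitude features match hand computation", {
  # [0, 6, 0, 6, 0] dB over 1 s: AmpVar 24 dB/s, 2 cycles, extent 6 dB
  af <- amplitudeFeatures(c(0, 6, 0, 6, 0), dur = 1)
  expect_equal(af$AmpVar, 24)
  expect_equal(af$AmpModRate, 2)
  expect_equal(af$AmpModExtent, 6)
  # flat contour: no variation, no measurable modulation
  flat <- amplitudeFeatures(rep(-20, 50), dur = 1)
  expect_equal(flat$AmpVar, 0)
  expect_true(is.na(flat$AmpModRate))
  expect_true(is.na(flat$AmpModExtent))
  # sub-threshold ripple does not count as modulation
  ripple <- amplitudeFeatures(rep(c(-20, -19), 25), dur = 1)
  expect_true(is.na(ripple$AmpModRate))
  expect_error(amplitudeFeatures(c(0), dur = 1), "2 contour frames")
})

test_that("average spectrum localizes tones and flattens noise", {
  sp <- averageSpectrum(toneCall(1000, dur = 1))
  expect_lt(abs(sp$freqs[which.max(sp$power)] - 1000), 20)
  # two tones: both dominate
  t <- seq(0, 1, by = 1 / 16000)
  two <- makeCall(0.4 * sin(2 * pi * 500 * t) + 0.4 * sin(2 * pi * 3000 * t))
  sp2 <- averageSpectrum(two)
  top2 <- sp2$freqs[order(sp2$power, decreasing = TRUE)[1:2]]
  expect_setequal(round(sort(top2) / 500) * 500, c(500, 3000))
  # long white-noise call: no bin dominates
  set.seed(42)
  spn <- averageSpectrum(makeCall(rnorm(32000, 0, 0.2)))
  expect_lt(max(spn$power), 5 * median(spn$power))
  expect_error(averageSpectrum(makeCall(numeric(1000))), "all-zero")
})

test_that("spectral features match closed-form cases", {
  # uniform power 0-1000 Hz
  uni <- list(freqs = seq(0, 1000, by = 1), power = rep(1, 1001))
  sf <- spectralFeatures(uni)
  expect_equal(sf$Q25, 250, tolerance = 2e-3)
  expect_equal(sf$Q50, 500, tolerance = 1e-3)
  expect_equal(sf$Q75, 750, tolerance = 1e-3)
  expect_equal(sf$WienEntropy, 0)
  # two equal bins: cumulative reaches 50% at the first
  sf2 <- spectralFeatures(list(freqs = c(100, 900), power = c(1, 1)))
  expect_equal(sf2$Q50, 100)
  # two-bin [1, 4]: entropy ln(geometric/arithmetic) = ln(2 / 2.5)
  sf3 <- spectralFeatures(list(freqs = c(100, 200), power = c(1, 4)))
  expect_equal(sf3$WienEntropy, log(0.8), tolerance = 1e-12)
  expect_equal(sf3$FPeak, 200)
  expect_error(spectralFeatures(list(freqs = 1:3, power = rep(0, 3))),
               "zero total power")
})

test_that("small spectra match the brute-force oracle", {
  # exhaustive hand computation for random spectra of <= 8 bins
  set.seed(7)
  for (i in 1:25) {
    nb <- sample(2:8, 1)
    freqs <- sort(runif(nb, 0, 8000))
    power <- runif(nb, 0.01, 5)
    sf <- spectralFeatures(list(freqs = freqs, power = power))
    cum <- cumsum(power) / sum(power)
    for (q in c(0.25, 0.50, 0.75)) {
      expected <- freqs[min(which(cum >= q))]
      got <- switch(as.character(q), "0.25" = sf$Q25, "0.5" = sf$Q50,
                    "0.75" = sf$Q75)
      expect_identical(got, expected)
    }
    expect_identical(sf$FPeak, freqs[which.max(power)])
    expect_equal(sf$WienEntropy,
                 min(mean(log(power)) - log(mean(power)), 0),
                 tolerance = 1e-12)
    expect_true(sf$Q25 <= sf$Q50 && sf$Q50 <= sf$Q75)
    expect_lte(sf$WienEntropy, 0)
  }
})

test_that("harmonicity orders tonal, mixed and noisy calls", {
  pure <- harmonicity(toneCall(200, dur = 1))
  expect_gte(pure, 30)
  set.seed(3)
  t <- seq(0, 1, by = 1 / 16000)
  noiseC <- makeCall(rnorm(length(t), 0, 0.2))
  noisy <- harmonicity(noiseC)
  expect_lte(noisy, 5)
  mix <- makeCall(0.4 * sin(2 * pi * 200 * t) + 0.28 * rnorm(length(t)))
  mixed <- harmonicity(mix)
  expect_gt(mixed, noisy)
  expect_lt(mixed, pure)
  expect_error(harmonicity(makeCall(rep(0.1, 100), 16000)), "too short")
})

test_that("call typing follows the age-specific Q50 cutoffs", {
  expect_equal(classifyCallType(3000, 1), "HF")
  expect_equal(classifyCallType(2200, 2), "HF")
  expect_equal(classifyCallType(896, 3), "LF")   # boundary -> LF
  expect_equal(classifyCallType(2414, 1), "LF")  # boundary -> LF
  expect_equal(classifyCallType(1000, 3), "HF")
  expect_equal(classifyCallType(2200, 1), "LF")
  expect_error(classifyCallType(1000, 4), "unknown age class")
  expect_error(classifyCallType(-5, 1))
})

test_that("spectral and modulation features are amplitude-scale invariant", {
  spec <- synthSpec(nPigs = 2, rngSeed = 77L)
  cl <- synthesizeCall(spec, "LF", "negative", "pig001", seed = 6L)
  half <- new("CallRecording", callId = "half", waveform = 0.5 * waveform(cl),
              sampleRate = sampleRate(cl), pigId = "pig001",
              teamId = "team1", ageDays = 20, ageClass = 1L,
              context = "isolation", valence = "negative")
  f1 <- spectralFeatures(averageSpectrum(cl))
  f2 <- spectralFeatures(averageSpectrum(half))
  expect_equal(f1[c("Q25", "Q50", "Q75", "FPeak", "WienEntropy")],
               f2[c("Q25", "Q50", "Q75", "FPeak", "WienEntropy")],
               tolerance = 1e-10)
  a1 <- amplitudeFeatures(intensityContour(cl), callDuration(cl))
  a2 <- amplitudeFeatures(intensityContour(half), callDuration(half))
  expect_equal(a1$AmpModRate, a2$AmpModRate)
  expect_equal(a1$AmpVar, a2$AmpVar, tolerance = 1e-8)
  expect_equal(a1$AmpModExtent, a2$AmpModExtent, tolerance = 1e-8)
})

test_that("the feature table has the contract columns and invariants", {
  fx <- directionFixture()
  ft <- fx$features
  need <- c("call_id", "pig_id", "team_id", "age_class", "context",
            "valence", "Dur", "AmpVar", "AmpModRate", "AmpModExtent",
            "Q25", "Q50", "Q75", "FPeak", "Harmonicity", "WienEntropy",
            "call_type")
  expect_true(all(need %in% names(ft)))
  expect_true(all(ft$Q25 <= ft$Q50 & ft$Q50 <= ft$Q75))
  expect_true(all(ft$WienEntropy <= 0))
  expect_true(all(ft$Dur > 0))
  expect_true(all(ft$call_type %in% c("LF", "HF")))
  # round trip through the CSV interchange format
  path <- tempfile(fileext = ".csv")
  writeFeatures(ft, path)
  back <- readFeatures(path)
  expect_equal(back$Q50, ft$Q50, tolerance = 1e-9)
  expect_equal(sum(is.na(back$AmpModRate)), sum(is.na(ft$AmpModRate)))
})
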