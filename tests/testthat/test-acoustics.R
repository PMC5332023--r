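test_that("the envelope tracks amplitude and vanishes on silence", {
  rate <- 44100
  t <- seq(0, 0.2, by = 1 / rate)
  tone <- waveform(0.8 * sin(2 * pi * 2500 * t), rate)
  env <- extractEnvelope(tone, smoothMs = 2)
  interior <- env[2000:(length(env) - 2000)]
  expect_true(all(abs(interior - 0.8) < 0.02 * 0.8))
  silence <- waveform(numeric(4410), rate)
  expect_true(all(extractEnvelope(silence) < 1e-12))
  expect_error(extractEnvelope(waveform(numeric(44), rate), smoothMs = 10),
               "longer than the recording")
})

test_that("pulse detection counts synthesized pulses exactly", {
  spec <- callSpec(nPulses = 17, pulsePeriodS = 0.19 / 17, carrierHz = 2655)
  w <- synthesizeCall(spec)
  env <- extractEnvelope(w, 2)
  peaks <- detectPulses(env, rateHz(w))
  expect_length(peaks, 17L)
  expect_true(all(diff(peaks) > 0))
  expect_identical(detectPulses(numeric(100), 44100), numeric(0))
  # peaks closer than the minimum separation collapse with a warning
  env2 <- c(0, 1, 0, 0.9, 0, 0)
  expect_warning(kept <- detectPulses(env2, 1000, relThreshold = 0.1,
                                      minSepS = 0.003), "merged")
  expect_length(kept, 1L)
})

test_that("note segmentation splits on gaps and pads by half a period", {
  pt <- c(seq(0, by = 0.008, length.out = 10),
          0.072 + 0.046 + seq(0, by = 0.008, length.out = 4))
  notes <- segmentNotes(pt, gapS = 0.02)
  expect_identical(nrow(notes), 2L)
  expect_identical(notes$nPulses, c(10L, 4L))
  expect_equal(notes$onsetS[2] - notes$offsetS[1], 0.046 - 0.008,
               tolerance = 1e-9)
  one <- segmentNotes(seq(0, by = 0.008, length.out = 6), gapS = 0.02)
  expect_identical(nrow(one), 1L)
  expect_error(segmentNotes(numeric(0)), class = "noCallDetected")
  expect_error(segmentNotes(c(0.3, 0.1)), "sorted")
})

test_that("note types follow the duration-and-pulse-count rule", {
  mk <- function(dur, n) data.frame(onsetS = 0, offsetS = dur, nPulses = n,
                                    firstPulseS = 0, lastPulseS = dur)
  expect_identical(classifyNotes(mk(0.19, 17))$noteType, "I")
  expect_identical(classifyNotes(mk(0.03, 4))$noteType, "II")
  expect_identical(classifyNotes(mk(0.06, 8))$noteType, "I")  # boundary
  expect_identical(classifyNotes(mk(0.06, 7))$noteType, "II")
  expect_identical(classifyNotes(mk(0.059, 8))$noteType, "II")
  notes <- rbind(mk(0.19, 17), mk(0.03, 4), mk(0.03, 4))
  notes <- classifyNotes(notes)
  expect_identical(classifyCall(notes), "advertisement")
  expect_identical(classifyCall(classifyNotes(rbind(mk(0.03, 4), mk(0.04, 5)))),
                   "aggressive")
})

test_that("spectral features resolve the carrier to within one FFT bin", {
  rate <- 44100
  bin <- rate / 1024
  expect_equal(round(bin, 1), 43.1)
  # bin-aligned pure tone, analysed over a hand-made note span
  f0 <- 64 * bin
  t <- seq(0, 0.5 - 1 / rate, by = 1 / rate)
  w <- waveform(0.9 * sin(2 * pi * f0 * t), rate)
  notes <- data.frame(onsetS = 0.05, offsetS = 0.45, nPulses = 1L,
                      firstPulseS = 0.05, lastPulseS = 0.45)
  sp <- spectralFeatures(w, notes)
  expect_equal(sp$binWidthHz, bin)
  expect_lt(abs(sp$dominantFreqHz - f0), bin)
  expect_lte(sp$freqBandwidthHz, 2 * bin + 1e-9)
  # independent windowed-FFT oracle for the peak bin
  seg <- samples(w)[4411:(4410 + 1024)]
  han <- 0.5 * (1 - cos(2 * pi * (0:1023) / 1023))
  oraclePeak <- (which.max(Mod(stats::fft(seg * han))[1:513]) - 1) * bin
  expect_equal(sp$dominantFreqHz, oraclePeak)
  # a pulsed tone keeps its dominant frequency at the carrier
  spec <- callSpec(nPulses = 17, pulsePeriodS = 0.19 / 17, carrierHz = 2655.37)
  feats <- extractCallFeatures(synthesizeCall(spec))
  expect_lt(abs(feats@features$dominant_freq_hz - 2655.37), bin)
  short <- data.frame(onsetS = 0.05, offsetS = 0.06, nPulses = 1L,
                      firstPulseS = 0.05, lastPulseS = 0.06)
  expect_error(spectralFeatures(w, short), "shorter than one FFT window")
})

test_that("full feature extraction round-trips synthesized calls", {
  # single-trill advertisement call (published one-note structure)
  arndti <- cladeCallSpec("A")
  fa <- extractCallFeatures(synthesizeCall(arndti))
  expect_identical(fa@features$n_notes, 1L)
  expect_identical(fa@features$n_pulses_call, 17L)
  expect_identical(fa@features$call_type, "advertisement")
  expect_lt(abs(fa@features$call_duration_s - 0.19),
            arndti@notes$pulsePeriodS[1])
  expect_lt(abs(fa@features$typeI_duration_s - 0.19),
            arndti@notes$pulsePeriodS[1])
  expect_true(is.na(fa@features$typeII_duration_s))

  # trill + two short secondary notes (published three-note structure)
  leuco <- leucoThreeNoteSpec()
  fl <- extractCallFeatures(synthesizeCall(leuco))
  expect_identical(fl@features$n_notes, 3L)
  expect_identical(fl@features$call_type, "advertisement")
  expect_identical(fl@segments$noteType, c("I", "II", "II"))
  expect_equal(fl@features$n_pulses_typeII, 4)
  expect_lt(abs(fl@features$inter_note_distance_s - 0.046), 0.01)
  expect_false(is.na(fl@features$typeII_duration_s))

  expect_error(extractCallFeatures(waveform(numeric(44100), 44100)),
               class = "noCallDetected")
})

test_that("note and pulse counts are recovered exactly across structures", {
  set.seed(21)
  for (rep in 1:8) {
    nNotes <- sample(1:4, 1)
    nPulses <- sample(3:18, nNotes, replace = TRUE)
    periods <- runif(nNotes, 0.006, 0.012)
    spec <- callSpec(nPulses = nPulses, pulsePeriodS = periods,
                     pulseDuty = runif(1, 0.4, 0.9),
                     interNoteGapS = runif(1, 0.03, 0.06),
                     carrierHz = runif(1, 2000, 3200),
                     amplitudes = runif(nNotes, 0.5, 1))
    feats <- extractCallFeatures(synthesizeCall(spec))
    expect_identical(feats@features$n_notes, nNotes)
    expect_identical(feats@segments$nPulses, nPulses)
  }
})

test_that("feature extraction is deterministic for identical input", {
  w <- synthesizeCall(cladeCallSpec("H"))
  f1 <- extractCallFeatures(w)
  f2 <- extractCallFeatures(w)
  expect_identical(f1@features, f2@features)
  expect_identical(f1@pulseTimesS, f2@pulseTimesS)
})
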