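#' Analysis configuration for call feature extraction
#'
#' Defaults chosen to separate the two note types of the
#' \emph{D. leucophyllatus--triangulum} complex: published Type I (pulsed
#' trill) notes are >= 0.08 s with >= 10.8 pulses while Type II notes are
#' <= 0.05 s with <= 6 pulses, so the Type I thresholds sit between the
#' two ranges.  The 1024-point FFT at 44.1 kHz gives the conventional
#' 43.1 Hz spectral resolution.
#'
#' @param smoothMs Envelope smoothing window, ms.
#' @param pulseRelThreshold Pulse peaks must exceed this fraction of the
#'   envelope maximum.
#' @param minPulseSepS Minimum separation between pulse peaks, s.
#' @param noteGapS Inter-pulse gap that starts a new note, s.
#' @param typeIMinDurationS,typeIMinPulses A note is Type I iff its
#'   duration and pulse count both reach these thresholds.
#' @param fftSize FFT window length, samples (Hann window, 50% hop).
#' @param bandRelDb Power floor relative to the frame peak (dB) defining
#'   the frequency bandwidth.
#' @param frameEnergyFloor Frames with RMS below this fraction of the
#'   loudest frame are treated as silent when picking the
#'   beginning/middle/end analysis frames.
#' @return Named list of parameters.
#' @export
acousticsConfig <- function(smoothMs = 2, pulseRelThreshold = 0.1,
                            minPulseSepS = 0.002, noteGapS = 0.02,
                            typeIMinDurationS = 0.06, typeIMinPulses = 8,
                            fftSize = 1024, bandRelDb = -20,
                            frameEnergyFloor = 0.05) {
  list(smoothMs = smoothMs, pulseRelThreshold = pulseRelThreshold,
       minPulseSepS = minPulseSepS, noteGapS = noteGapS,
       typeIMinDurationS = typeIMinDurationS, typeIMinPulses = typeIMinPulses,
       fftSize = fftSize, bandRelDb = bandRelDb,
       frameEnergyFloor = frameEnergyFloor,
       window = "hann", hopFraction = 0.5)
}

.noCallDetected <- function(msg = "no call detected in the recording") {
  stop(structure(class = c("noCallDetected", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Amplitude envelope of a waveform
#'
#' Magnitude of the analytic signal (Hilbert transform via FFT), smoothed
#' with a centred moving average.  Same length as the input,
#' non-negative.
#'
#' @param w A [Waveform-class].
#' @param smoothMs Smoothing window in milliseconds (default 2).
#' @return Numeric vector of envelope values.
#' @export
extractEnvelope <- function(w, smoothMs = 2) {
  stopifnot(is(w, "Waveform"))
  x <- samples(w)
  n <- length(x)
  if (smoothMs / 1000 > durationS(w))
    stop("smoothing window is longer than the recording")
  # analytic signal: zero out negative frequencies, double positives
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  win <- max(1L, round(smoothMs / 1000 * rateHz(w)))
  if (win > 1L) {
    k <- rep(1 / win, win)
    padded <- c(rep(env[1L], win), env, rep(env[n], win))
    sm <- stats::filter(padded, k, sides = 2)
    env <- as.numeric(sm[(win + 1L):(win + n)])
  }
  pmax(env, 0)
}

#' Detect pulse peaks in an envelope
#'
#' Local maxima above a relative threshold, subject to a minimum peak
#' separation (closer peaks are pruned keeping the higher one, with a
#' warning).
#'
#' @param env Envelope vector (from [extractEnvelope()]).
#' @param rateHz Sampling rate of the envelope, Hz.
#' @param relThreshold Fraction of the envelope maximum a peak must
#'   exceed (default 0.1).
#' @param minSepS Minimum peak separation in seconds (default 0.002).
#' @return Numeric vector of pulse peak times in seconds (possibly
#'   empty; an all-zero envelope yields no peaks, not an error).
#' @export
detectPulses <- function(env, rateHz, relThreshold = 0.1, minSepS = 0.002) {
  if (!length(env)) stop("empty envelope")
  mx <- max(env)
  if (mx <= 0) return(numeric(0))
  thr <- relThreshold * mx
  n <- length(env)
  if (n < 3L) return(numeric(0))
  core <- env[2:(n - 1L)]
  isPeak <- core > thr & core >= env[1:(n - 2L)] & core >= env[3:n]
  # plateaus: keep only the first sample of a run of equal values
  idx <- which(isPeak) + 1L
  if (length(idx) > 1L)
    idx <- idx[c(TRUE, env[idx[-1L]] != env[idx[-length(idx)]] |
                   diff(idx) > 1L)]
  if (!length(idx)) return(numeric(0))
  minSep <- round(minSepS * rateHz)
  keep <- logical(length(idx))
  dropped <- FALSE
  for (o in order(env[idx], decreasing = TRUE)) {
    if (any(keep & abs(idx - idx[o]) < minSep)) { dropped <- TRUE; next }
    keep[o] <- TRUE
  }
  if (dropped)
    warning("pulse peaks closer than the minimum separation were merged")
  sort((idx[keep] - 1L) / rateHz)
}

#' Segment pulse times into notes
#'
#' Consecutive pulses separated by more than \code{gapS} start a new
#' note.  Note onsets/offsets are the first/last pulse time padded by
#' half the local pulse period (median within-note inter-pulse interval).
#'
#' @param pulseTimes Sorted pulse peak times, seconds.
#' @param gapS Gap threshold in seconds (default 0.02).
#' @return data.frame with one row per note: \code{onsetS},
#'   \code{offsetS}, \code{nPulses}, \code{firstPulseS},
#'   \code{lastPulseS}.  An empty pulse list signals a
#'   \code{noCallDetected} error.
#' @export
segmentNotes <- function(pulseTimes, gapS = 0.02) {
  if (!length(pulseTimes)) .noCallDetected()
  if (is.unsorted(pulseTimes)) stop("pulse times must be sorted")
  noteId <- cumsum(c(1, diff(pulseTimes) > gapS))
  allDiffs <- diff(pulseTimes)
  withinDiffs <- allDiffs[allDiffs <= gapS]
  fallback <- if (length(withinDiffs)) stats::median(withinDiffs) else gapS / 2
  notes <- lapply(split(pulseTimes, noteId), function(pt) {
    period <- if (length(pt) > 1L) stats::median(diff(pt)) else fallback
    data.frame(onsetS = pt[1L] - period / 2,
               offsetS = pt[length(pt)] + period / 2,
               nPulses = length(pt),
               firstPulseS = pt[1L], lastPulseS = pt[length(pt)])
  })
  out <- do.call(rbind, notes)
  rownames(out) <- NULL
  out$onsetS <- pmax(out$onsetS, 0)
  out
}

#' Classify notes as Type I or Type II
#'
#' A note is a Type I pulsed trill iff its duration and pulse count both
#' reach the configured thresholds (defaults 0.06 s and 8 pulses, chosen
#' between the published Type I and Type II ranges); otherwise Type II.
#'
#' @param notes data.frame from [segmentNotes()].
#' @param minDurationS,minPulses Type I thresholds.
#' @return The data.frame with an added \code{noteType} column
#'   (\code{"I"} or \code{"II"}).
#' @export
classifyNotes <- function(notes, minDurationS = 0.06, minPulses = 8) {
  if (!nrow(notes)) stop("at least one note required")
  dur <- notes$offsetS - notes$onsetS
  notes$noteType <- ifelse(dur >= minDurationS & notes$nPulses >= minPulses,
                           "I", "II")
  notes
}

#' Classify a call as advertisement or aggressive
#'
#' Advertisement calls contain a Type I trill (optionally followed by
#' Type II notes); calls made only of Type II notes are aggressive.
#'
#' @param notes data.frame with a \code{noteType} column (from
#'   [classifyNotes()]).
#' @return \code{"advertisement"} or \code{"aggressive"}.
#' @export
classifyCall <- function(notes) {
  if (!nrow(notes)) stop("at least one note required")
  if (any(notes$noteType == "I")) "advertisement" else "aggressive"
}

# Hann-windowed power spectra of the call span.  Returns the bin
# frequencies and a bins x frames power matrix plus frame centre times.
.callSpectrogram <- function(w, spanIdx, fftSize, hopFraction) {
  x <- samples(w)[spanIdx]
  if (length(x) < fftSize)
    stop("call is shorter than one FFT window (", fftSize, " samples)")
  hop <- max(1L, round(fftSize * hopFraction))
  starts <- seq(1L, length(x) - fftSize + 1L, by = hop)
  if (starts[length(starts)] + fftSize - 1L < length(x))
    starts <- c(starts, length(x) - fftSize + 1L)  # cover the call end
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(fftSize) - 1L) / (fftSize - 1L)))
  nBins <- fftSize %/% 2L + 1L
  pow <- vapply(starts, function(s) {
    seg <- x[s + seq_len(fftSize) - 1L] * win
    Mod(stats::fft(seg)[seq_len(nBins)])^2
  }, numeric(nBins))
  rate <- rateHz(w)
  list(freqs = (seq_len(nBins) - 1L) * rate / fftSize,
       power = pow,
       timesS = (spanIdx[1L] - 1L + starts - 1L + fftSize / 2) / rate)
}

#' Spectral features of a call
#'
#' Dominant frequency and frequency bandwidth from Hann-windowed
#' 1024-point FFT frames (50% hop) over the call span.  The dominant
#' frequency is the mean of the peak-bin frequency at the beginning,
#' middle and end analysis frames of the call (frames with negligible
#' energy, e.g. inside inter-note gaps, are skipped); the bandwidth is
#' the spread of frequencies whose power comes within \code{bandRelDb}
#' of the frame peak, across the call's voiced frames.  Both are
#' quantized to the bin width \code{rate / fftSize} (43.1 Hz at
#' 44.1 kHz).
#'
#' @param w A [Waveform-class].
#' @param notes Note data.frame (from [segmentNotes()]); the call span is
#'   the onset of the first note to the offset of the last.
#' @param config List from [acousticsConfig()].
#' @return List with \code{dominantFreqHz}, \code{freqBandwidthHz},
#'   \code{binWidthHz}.
#' @export
spectralFeatures <- function(w, notes, config = acousticsConfig()) {
  stopifnot(is(w, "Waveform"), nrow(notes) >= 1L)
  rate <- rateHz(w)
  i0 <- max(1L, floor(notes$onsetS[1L] * rate) + 1L)
  i1 <- min(length(samples(w)), ceiling(notes$offsetS[nrow(notes)] * rate))
  sg <- .callSpectrogram(w, i0:i1, config$fftSize, config$hopFraction)
  rms <- sqrt(colMeans(sg$power))
  voiced <- which(rms >= config$frameEnergyFloor * max(rms))
  if (!length(voiced)) .noCallDetected("call frames carry no energy")
  pick <- voiced[unique(c(1L, ceiling(length(voiced) / 2), length(voiced)))]
  peakFreq <- vapply(pick, function(j) sg$freqs[which.max(sg$power[, j])],
                     numeric(1))
  floorFactor <- 10^(config$bandRelDb / 10)
  bandFreqs <- unlist(lapply(voiced, function(j) {
    p <- sg$power[, j]
    sg$freqs[p >= floorFactor * max(p)]
  }))
  list(dominantFreqHz = mean(peakFreq),
       freqBandwidthHz = max(bandFreqs) - min(bandFreqs),
       binWidthHz = rate / config$fftSize)
}

#' Extract the full set of call features from a recording
#'
#' Composes envelope extraction, pulse detection, note segmentation,
#' note- and call-type classification, and spectral analysis into the
#' standard per-call variable set: call duration, note/pulse counts, rise
#' times, Type I/II note statistics, inter-note and inter-pulse
#' distances, dominant frequency and bandwidth, and the
#' advertisement/aggressive label.  Rise times run from the call (or
#' Type I note) onset to the envelope maximum within the span; Type II
#' fields are \code{NA} when no Type II note is present.
#'
#' @param w A [Waveform-class].
#' @param config List from [acousticsConfig()].
#' @return A [CallFeatures-class].  Signals a \code{noCallDetected}
#'   condition for silent input.
#' @examples
#' w <- synthesizeCall(callSpec(17, 0.19 / 17, carrierHz = 2655))
#' extractCallFeatures(w)
#' @export
extractCallFeatures <- function(w, config = acousticsConfig()) {
  stopifnot(is(w, "Waveform"))
  env <- extractEnvelope(w, config$smoothMs)
  rate <- rateHz(w)
  pulses <- detectPulses(env, rate, config$pulseRelThreshold,
                         config$minPulseSepS)
  notes <- segmentNotes(pulses, config$noteGapS)
  notes <- classifyNotes(notes, config$typeIMinDurationS,
                         config$typeIMinPulses)
  callType <- classifyCall(notes)
  spanStart <- notes$onsetS[1L]
  spanEnd <- notes$offsetS[nrow(notes)]
  envMaxAt <- function(fromS, toS) {
    idx <- max(1L, floor(fromS * rate) + 1L):min(length(env),
                                                 ceiling(toS * rate))
    (idx[which.max(env[idx])] - 1L) / rate
  }
  riseCall <- envMaxAt(spanStart, spanEnd) - spanStart
  typeI <- notes[notes$noteType == "I", , drop = FALSE]
  typeII <- notes[notes$noteType == "II", , drop = FALSE]
  firstI <- if (nrow(typeI)) typeI[1L, , drop = FALSE] else NULL
  interNote <- if (nrow(notes) > 1L)
    mean(notes$onsetS[-1L] - notes$offsetS[-nrow(notes)]) else NA_real_
  ipd <- unlist(lapply(split(pulses, cumsum(c(1, diff(pulses) >
                                                config$noteGapS))), diff))
  spec <- spectralFeatures(w, notes, config)
  features <- list(
    call_duration_s = spanEnd - spanStart,
    n_notes = nrow(notes),
    rise_time_call_s = riseCall,
    n_pulses_call = sum(notes$nPulses),
    typeI_duration_s = if (!is.null(firstI))
      firstI$offsetS - firstI$onsetS else NA_real_,
    n_pulses_typeI = if (!is.null(firstI)) firstI$nPulses else NA_integer_,
    rise_time_typeI_s = if (!is.null(firstI))
      envMaxAt(firstI$onsetS, firstI$offsetS) - firstI$onsetS else NA_real_,
    typeII_duration_s = if (nrow(typeII))
      mean(typeII$offsetS - typeII$onsetS) else NA_real_,
    n_pulses_typeII = if (nrow(typeII)) mean(typeII$nPulses) else NA_real_,
    inter_note_distance_s = interNote,
    dominant_freq_hz = spec$dominantFreqHz,
    freq_bandwidth_hz = spec$freqBandwidthHz,
    inter_pulse_distance_s = if (length(ipd)) mean(ipd) else NA_real_,
    call_type = callType)
  new("CallFeatures", features = features, segments = notes,
      pulseTimesS = pulses,
      params = c(config, list(binWidthHz = spec$binWidthHz)))
}

#' Extract features from a set of WAV files
#'
#' @param paths Character vector of WAV paths.
#' @param config List from [acousticsConfig()].
#' @return data.frame with one row per readable call (column \code{file}
#'   first); recordings where no call is detected are skipped with a
#'   warning.
#' @export
extractCallFeatureTable <- function(paths, config = acousticsConfig()) {
  rows <- lapply(paths, function(p) {
    feats <- tryCatch(extractCallFeatures(readWav(p), config),
                      noCallDetected = function(e) NULL)
    if (is.null(feats)) {
      warning("no call detected in ", p)
      return(NULL)
    }
    cbind(data.frame(file = basename(p), stringsAsFactors = FALSE),
          as.data.frame(feats))
  })
  do.call(rbind, rows)
}
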