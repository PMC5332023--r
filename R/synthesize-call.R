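#' Build a call specification
#'
#' @param nPulses Integer vector, pulses per note (one entry per note).
#' @param pulsePeriodS Pulse period per note, seconds (recycled).
#' @param pulseDuty Fraction of the pulse period occupied by the
#'   raised-cosine pulse window, in (0, 1] (recycled; default 0.7).
#' @param interNoteGapS Silent gap between notes, seconds.
#' @param carrierHz Carrier frequency, Hz (must be below Nyquist).
#' @param sampleRateHz Sampling rate, Hz; the default 44100 gives the
#'   43.1 Hz spectral resolution of a 1024-point FFT.
#' @param amplitudes Per-note relative peak amplitude in (0, 1]
#'   (recycled; default 1).
#' @return A [CallSpec-class].
#' @examples
#' # a one-note pulsed trill: 17 pulses at ~89 pulses/s
#' callSpec(nPulses = 17, pulsePeriodS = 0.19 / 17, carrierHz = 2655)
#' @export
callSpec <- function(nPulses, pulsePeriodS, pulseDuty = 0.7,
                     interNoteGapS = 0.046, carrierHz, sampleRateHz = 44100,
                     amplitudes = 1) {
  if (length(nPulses) < 1L) stop("a call must contain at least one note")
  n <- length(nPulses)
  notes <- data.frame(nPulses = as.integer(nPulses),
                      pulsePeriodS = rep_len(pulsePeriodS, n),
                      pulseDuty = rep_len(pulseDuty, n))
  new("CallSpec", notes = notes, interNoteGapS = interNoteGapS,
      carrierHz = carrierHz, sampleRateHz = sampleRateHz,
      amplitudes = rep_len(amplitudes, n))
}

#' Synthesize a pulsed frog call
#'
#' Renders a [CallSpec-class] as audio: each pulse is a carrier sinusoid
#' gated by a raised-cosine (Hann) window of width
#' \code{pulseDuty * pulsePeriodS}, pulses within a note are contiguous at
#' the pulse period, and notes are separated by silent gaps.  Optional
#' additive white noise models recording noise.
#'
#' @param spec A [CallSpec-class].
#' @param seed Integer seed (used only when \code{noiseSd > 0}).
#' @param noiseSd Standard deviation of additive white Gaussian noise
#'   relative to full scale; 0 (default) for a noiseless call.
#' @param padS Leading/trailing silence, seconds (default 0.05).
#' @return A [Waveform-class]; peak |amplitude| <= 1.
#' @examples
#' w <- synthesizeCall(callSpec(17, 0.19 / 17, carrierHz = 2655), seed = 1)
#' durationS(w)
#' @export
synthesizeCall <- function(spec, seed = 1L, noiseSd = 0, padS = 0.05) {
  stopifnot(is(spec, "CallSpec"))
  validObject(spec)
  rate <- spec@sampleRateHz
  pad <- numeric(round(padS * rate))
  pieces <- list(pad)
  gap <- numeric(round(spec@interNoteGapS * rate))
  for (k in seq_len(nrow(spec@notes))) {
    m <- spec@notes$nPulses[k]
    period <- spec@notes$pulsePeriodS[k]
    duty <- spec@notes$pulseDuty[k]
    perN <- round(period * rate)
    widthN <- max(2L, round(duty * period * rate))
    noteN <- (m - 1L) * perN + widthN
    t <- (seq_len(noteN) - 1L) / rate
    env <- numeric(noteN)
    for (j in seq_len(m)) {
      i0 <- (j - 1L) * perN
      idx <- i0 + seq_len(widthN)
      win <- 0.5 * (1 - cos(2 * pi * (seq_len(widthN) - 1L) / (widthN - 1L)))
      env[idx] <- pmax(env[idx], win)
    }
    note <- spec@amplitudes[k] * env * sin(2 * pi * spec@carrierHz * t)
    if (k > 1L) pieces <- c(pieces, list(gap))
    pieces <- c(pieces, list(note))
  }
  pieces <- c(pieces, list(pad))
  x <- unlist(pieces, use.names = FALSE)
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    x <- x + stats::rnorm(length(x), sd = noiseSd)
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  waveform(x, rate)
}

#' Simulate a cloud of occurrence points
#'
#' Gaussian scatter of lon/lat occurrence records around a centre, used as
#' toy input for range estimation.
#'
#' @param centerLon,centerLat Centre of the cloud, WGS84 decimal degrees.
#' @param n Number of points.
#' @param spreadDeg Standard deviation of the scatter, degrees.
#' @param seed Integer seed.
#' @return data.frame with columns \code{lon}, \code{lat}.
#' @export
simulateOccurrences <- function(centerLon, centerLat, n, spreadDeg = 1,
                                seed = 1L) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  data.frame(lon = stats::rnorm(n, centerLon, spreadDeg),
             lat = stats::rnorm(n, centerLat, spreadDeg))
}
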