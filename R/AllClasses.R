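#' @import methods
NULL

#' Mono audio waveform
#'
#' Container for a single-channel audio signal with amplitudes on
#' \code{[-1, 1]} and its sampling rate.
#'
#' @slot samples Numeric vector of amplitudes in \code{[-1, 1]}.
#' @slot rateHz Sampling rate in Hz (single positive number).
#'
#' @seealso [synthesizeCall()], [readWav()], [writeWav()]
#' @exportClass Waveform
setClass("Waveform",
  representation(samples = "numeric", rateHz = "numeric"))

setValidity("Waveform", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) ||
      object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "waveform must contain at least one sample")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-9)
    msg <- c(msg, "samples must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a Waveform
#'
#' @param samples Numeric vector of amplitudes in \code{[-1, 1]}.
#' @param rateHz Sampling rate in Hz.
#' @return A [Waveform-class] object.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1/8000)), 8000)
#' durationS(w)
#' @export
waveform <- function(samples, rateHz) {
  new("Waveform", samples = as.numeric(samples), rateHz = as.numeric(rateHz))
}

#' Synthetic call specification
#'
#' Describes the note/pulse structure of a frog call in the
#' \emph{D. leucophyllatus--triangulum} complex: an ordered set of pulsed
#' notes (each a train of raised-cosine-gated carrier pulses), separated by
#' silent gaps.  Advertisement calls start with a long pulsed trill (Type I
#' note) optionally followed by shorter Type II notes; aggressive calls are
#' series of Type II notes.
#'
#' @slot notes data.frame with one row per note and columns
#'   \code{nPulses}, \code{pulsePeriodS}, \code{pulseDuty}.
#' @slot interNoteGapS Silent gap between consecutive notes, seconds.
#' @slot carrierHz Carrier (dominant) frequency, Hz.
#' @slot sampleRateHz Sampling rate of the synthesized waveform, Hz.
#' @slot amplitudes Per-note relative peak amplitudes in (0, 1].
#'
#' @seealso [callSpec()], [synthesizeCall()]
#' @exportClass CallSpec
setClass("CallSpec",
  representation(notes = "data.frame", interNoteGapS = "numeric",
                 carrierHz = "numeric", sampleRateHz = "numeric",
                 amplitudes = "numeric"))

setValidity("CallSpec", function(object) {
  msg <- character()
  nt <- object@notes
  if (nrow(nt) < 1L)
    msg <- c(msg, "a call must contain at least one note")
  req <- c("nPulses", "pulsePeriodS", "pulseDuty")
  if (!all(req %in% names(nt))) {
    msg <- c(msg, paste("notes must have columns", paste(req, collapse = ", ")))
  } else {
    if (any(nt$nPulses < 1L)) msg <- c(msg, "every note needs nPulses >= 1")
    if (any(nt$pulsePeriodS <= 0)) msg <- c(msg, "pulsePeriodS must be > 0")
    if (any(nt$pulseDuty <= 0 | nt$pulseDuty > 1))
      msg <- c(msg, "pulseDuty must lie in (0, 1]")
  }
  if (length(object@interNoteGapS) != 1L || object@interNoteGapS <= 0)
    msg <- c(msg, "interNoteGapS must be a single positive number")
  if (length(object@carrierHz) != 1L || object@carrierHz <= 0)
    msg <- c(msg, "carrierHz must be positive")
  if (object@carrierHz >= object@sampleRateHz / 2)
    msg <- c(msg, "carrierHz must be below the Nyquist frequency")
  if (length(object@amplitudes) != nrow(nt))
    msg <- c(msg, "one amplitude per note required")
  else if (any(object@amplitudes <= 0 | object@amplitudes > 1))
    msg <- c(msg, "amplitudes must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pairwise p-distance matrix
#'
#' Square symmetric matrix of uncorrected p-distances between aligned
#' sequences, together with the per-pair count of compared sites (pairwise
#' deletion of gaps and ambiguities).  Pairs with zero compared sites are
#' \code{NA} in \code{d} (flagged missing, never reported as 0).
#'
#' @slot d Numeric matrix of distances in \code{[0, 1]}; \code{NA} marks a
#'   pair with no comparable sites.
#' @slot sites Integer matrix of compared-site counts per pair.
#'
#' @seealso [pairwisePDistance()], [cladePairSummary()]
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(d = "matrix", sites = "matrix"))

setValidity("DistanceMatrix", function(object) {
  msg <- character()
  d <- object@d
  if (nrow(d) != ncol(d)) msg <- c(msg, "distance matrix must be square")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "distance matrix must carry sequence ids as dimnames")
  if (!isTRUE(all.equal(d, t(d)))) msg <- c(msg, "distances must be symmetric")
  if (any(diag(d) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(d < 0 | d > 1, na.rm = TRUE))
    msg <- c(msg, "distances must lie in [0, 1]")
  if (!identical(dim(object@sites), dim(d)))
    msg <- c(msg, "sites matrix must match the distance matrix dimensions")
  if (length(msg)) msg else TRUE
})

#' Extracted call features
#'
#' The acoustic variables extracted from one call: call duration, note and
#' pulse counts, rise times, Type I/Type II note statistics, inter-note and
#' inter-pulse distances, dominant frequency (averaged over the beginning,
#' middle and end of the call) and frequency bandwidth, plus the
#' advertisement/aggressive call-type classification.  Type II fields are
#' \code{NA} when the call contains no Type II note.
#'
#' @slot features Named list of the call variables (see
#'   [callFeatureNames()]).
#' @slot segments data.frame of note segments: onset, offset, pulse count,
#'   note type.
#' @slot pulseTimesS Numeric vector of detected pulse peak times, seconds.
#' @slot params Named list of the analysis parameters used (window type,
#'   FFT size, thresholds), recorded for reproducibility.
#'
#' @seealso [extractCallFeatures()]
#' @exportClass CallFeatures
setClass("CallFeatures",
  representation(features = "list", segments = "data.frame",
                 pulseTimesS = "numeric", params = "list"))

#' Correlation-matrix PCA result
#'
#' Eigendecomposition of the correlation matrix of call variables, with
#' components retained by the eigenvalue > 1 rule.  Percent variance per
#' component is \code{eigenvalue / nVariables * 100}; the sign of each
#' loading column is fixed so that its largest-magnitude entry is positive.
#'
#' @slot loadings Variables x components matrix of loadings (eigenvectors).
#' @slot eigenvalues Eigenvalues in decreasing order; they sum to the
#'   number of variables.
#' @slot percentVariance Percent of total variance per component.
#' @slot retained Number of components with eigenvalue > 1.
#' @slot scores Rows x retained-components matrix of standardized scores.
#'
#' @seealso [correlationPca()], [pcGroupTests()]
#' @exportClass PCAResult
setClass("PCAResult",
  representation(loadings = "matrix", eigenvalues = "numeric",
                 percentVariance = "numeric", retained = "integer",
                 scores = "matrix"))

setValidity("PCAResult", function(object) {
  msg <- character()
  p <- length(object@eigenvalues)
  if (ncol(object@loadings) != p)
    msg <- c(msg, "one loading column per eigenvalue required")
  if (abs(sum(object@eigenvalues) - nrow(object@loadings)) > 1e-6)
    msg <- c(msg, "eigenvalues of a correlation PCA must sum to the number of variables")
  if (object@retained > p) msg <- c(msg, "cannot retain more components than exist")
  if (length(msg)) msg else TRUE
})
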