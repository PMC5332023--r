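#' Accessors for waveform objects
#'
#' @param x A [Waveform-class].
#' @return \code{samples()} the amplitude vector, \code{rateHz()} the
#'   sampling rate in Hz, \code{durationS()} the duration in seconds.
#' @name waveform-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname waveform-accessors
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))

#' @rdname waveform-accessors
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' @rdname waveform-accessors
setMethod("samples", "Waveform", function(x) x@samples)

#' @rdname waveform-accessors
setMethod("rateHz", "Waveform", function(x) x@rateHz)

#' @rdname waveform-accessors
setMethod("durationS", "Waveform", function(x) length(x@samples) / x@rateHz)

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(object@samples), object@rateHz,
              durationS(object), max(abs(object@samples))))
})

#' Accessors for distance matrices
#'
#' @param x A [DistanceMatrix-class].
#' @return \code{distances()} the symmetric p-distance matrix (\code{NA}
#'   for pairs with no comparable sites); \code{comparedSites()} the
#'   per-pair compared-site counts.
#' @name distancematrix-accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname distancematrix-accessors
#' @export
setGeneric("comparedSites", function(x) standardGeneric("comparedSites"))

#' @rdname distancematrix-accessors
setMethod("distances", "DistanceMatrix", function(x) x@d)

#' @rdname distancematrix-accessors
setMethod("comparedSites", "DistanceMatrix", function(x) x@sites)

setMethod("show", "DistanceMatrix", function(object) {
  n <- nrow(object@d)
  off <- object@d[upper.tri(object@d)]
  cat(sprintf("DistanceMatrix: %d sequences, %d pairs", n, length(off)))
  if (length(off))
    cat(sprintf(", p in [%.4g, %.4g]", min(off, na.rm = TRUE),
                max(off, na.rm = TRUE)))
  if (anyNA(off)) cat(sprintf(", %d pairs missing", sum(is.na(off))))
  cat("\n")
})

setMethod("show", "PCAResult", function(object) {
  cat(sprintf(
    "Correlation-matrix PCA: %d variables, %d components retained (eigenvalue > 1)\n",
    nrow(object@loadings), object@retained))
  ev <- object@eigenvalues[seq_len(max(object@retained, 1L))]
  pv <- object@percentVariance[seq_len(max(object@retained, 1L))]
  for (i in seq_along(ev))
    cat(sprintf("  PC %d: eigenvalue %.2f (%.2f%% of variance)\n", i, ev[i], pv[i]))
})

setMethod("show", "CallSpec", function(object) {
  cat(sprintf("CallSpec: %d note(s), carrier %g Hz @ %g Hz sampling\n",
              nrow(object@notes), object@carrierHz, object@sampleRateHz))
  print(object@notes)
})

setMethod("show", "CallFeatures", function(object) {
  f <- object@features
  cat(sprintf("CallFeatures: %s call, %d note(s), %d pulses, %.3f s\n",
              f$call_type, f$n_notes, f$n_pulses_call, f$call_duration_s))
  cat(sprintf("  dominant frequency %.1f Hz, bandwidth %.1f Hz\n",
              f$dominant_freq_hz, f$freq_bandwidth_hz))
})

#' Names of the extracted call variables
#'
#' The acoustic variables reported per call, in reporting order: call
#' duration, number of notes, rise time of the call, number of pulses per
#' call, Type I note duration/pulses/rise time, Type II note
#' duration/pulses, distance between notes, average dominant frequency,
#' frequency bandwidth, distance between pulses, and the call-type label.
#'
#' @return Character vector of feature names.
#' @export
callFeatureNames <- function() {
  c("call_duration_s", "n_notes", "rise_time_call_s", "n_pulses_call",
    "typeI_duration_s", "n_pulses_typeI", "rise_time_typeI_s",
    "typeII_duration_s", "n_pulses_typeII", "inter_note_distance_s",
    "dominant_freq_hz", "freq_bandwidth_hz", "inter_pulse_distance_s",
    "call_type")
}

#' Coerce call features to a one-row data.frame
#'
#' @param x A [CallFeatures-class].
#' @param row.names,optional Ignored, present for the generic.
#' @param ... Ignored.
#' @return One-row data.frame with a column per call variable.
#' @method as.data.frame CallFeatures
#' @export
as.data.frame.CallFeatures <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  f <- x@features[callFeatureNames()]
  f[vapply(f, is.null, logical(1))] <- NA
  as.data.frame(f, stringsAsFactors = FALSE)
}
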