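#' Accessors for Recording and result objects
#'
#' `soundPa()` and `ppgSignal()` return the two channels, `sampleRate()` the
#' shared sampling rate in Hz, `duration()` the length in seconds, and
#' `ptciMax()` the detector score of a [PTCIResult-class].
#'
#' @param x a [Recording-class] or [PTCIResult-class] object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("soundPa", function(x) standardGeneric("soundPa"))
#' @rdname accessors
#' @export
setGeneric("ppgSignal", function(x) standardGeneric("ppgSignal"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("ptciMax", function(x) standardGeneric("ptciMax"))
#' @rdname accessors
#' @export
setGeneric("bandPtci", function(x) standardGeneric("bandPtci"))
#' @rdname accessors
#' @export
setGeneric("heartRateHz", function(x) standardGeneric("heartRateHz"))
#' @rdname accessors
#' @export
setGeneric("keepMask", function(x) standardGeneric("keepMask"))
#' @rdname accessors
#' @export
setGeneric("peakIndices", function(x) standardGeneric("peakIndices"))

#' @rdname accessors
setMethod("soundPa", "Recording", function(x) x@sound)
#' @rdname accessors
setMethod("ppgSignal", "Recording", function(x) x@ppg)
#' @rdname accessors
setMethod("sampleRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("duration", "Recording", function(x) length(x@sound) / x@fs)
#' @rdname accessors
setMethod("ptciMax", "PTCIResult", function(x) x@ptciMax)
#' @rdname accessors
setMethod("bandPtci", "PTCIResult", function(x) x@bandPtci)
#' @rdname accessors
setMethod("heartRateHz", "PTCIResult", function(x) x@heartRateHz)
#' @rdname accessors
setMethod("keepMask", "BeatSegmentation", function(x) x@keepMask)
#' @rdname accessors
setMethod("peakIndices", "BeatSegmentation", function(x) x@peakIndices)

setMethod("show", "Recording", function(object) {
    cat(sprintf("Recording: %s (%s ear)\n", object@subject, object@side))
    cat(sprintf("  %d samples at %g Hz (%.2f s)\n", length(object@sound),
                object@fs, length(object@sound) / object@fs))
    if (length(object@sound)) {
        r <- sqrt(mean(object@sound^2))
        lvl <- if (r > 0) sprintf("%.1f dB SPL", 20 * log10(r / 2e-5)) else "-Inf dB SPL"
        cat(sprintf("  sound RMS: %s\n", lvl))
    }
    if (!is.na(object@label))
        cat(sprintf("  label: %s\n",
                    if (object@label) "pulsatile" else "non-pulsatile"))
    invisible(object)
})

setMethod("show", "Calibration", function(object) {
    cat(sprintf("Calibration: %g counts/Pa", object@countsPerPascal))
    if (nzchar(object@referenceNote))
        cat(sprintf(" (%s)", object@referenceNote))
    cat("\n")
    invisible(object)
})

setMethod("show", "BeatSegmentation", function(object) {
    n <- nrow(object@segments)
    cat(sprintf("BeatSegmentation: %d peaks, %d segments (%d kept, %d rejected)\n",
                length(object@peakIndices), n, sum(object@keepMask),
                sum(!object@keepMask)))
    cat(sprintf("  RMS threshold: %.2f dB SPL (median + %g dB margin)\n",
                object@rmsThresholdDb, object@marginDb))
    invisible(object)
})

setMethod("show", "PTCIResult", function(object) {
    cat("PTCIResult\n")
    cat(sprintf("  heart rate: %.3f Hz (%.0f bpm)\n", object@heartRateHz,
                60 * object@heartRateHz))
    cat("  PTCI per octave band:\n")
    for (i in seq_along(object@bandPtci))
        cat(sprintf("    %5s Hz: %.3f\n", names(object@bandPtci)[i],
                    object@bandPtci[i]))
    cat(sprintf("  PTCI_max: %.3f (band %g Hz)\n", object@ptciMax,
                object@ptciMaxBandHz))
    invisible(object)
})

#' Tabulate a PTCIResult
#'
#' One row per octave band with the band center and its PTCI.
#'
#' @param x a [PTCIResult-class].
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return data.frame with columns `center_hz`, `ptci`.
#' @export
as.data.frame.PTCIResult <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    data.frame(center_hz = as.numeric(names(x@bandPtci)),
               ptci = unname(x@bandPtci))
}
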