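#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ptcoherence, .registration = TRUE
NULL

#' Recording: paired ear-canal sound and photoplethysmogram
#'
#' Container for one simultaneously sampled two-channel measurement: the
#' ear-canal microphone signal in pascals and the fingertip PPG in arbitrary
#' units, sharing a single sampling rate. The PPG is deliberately left
#' uncalibrated: it serves only as the heartbeat timing reference for the
#' coherence analysis.
#'
#' @slot sound numeric vector, calibrated sound pressure in Pa.
#' @slot ppg numeric vector, PPG samples in arbitrary units; same length as
#'   `sound`.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot subject character(1), subject identifier.
#' @slot side character(1), one of `"left"`, `"right"`, `"unknown"`.
#' @slot label logical(1), optional ground-truth / clinical annotation for
#'   pulsatility (`NA` when unknown).
#'
#' @seealso [Recording()], [readRecording()], [computePtci()]
#' @export
setClass("Recording",
    representation(
        sound   = "numeric",
        ppg     = "numeric",
        fs      = "numeric",
        subject = "character",
        side    = "character",
        label   = "logical"
    ),
    prototype(subject = "unknown", side = "unknown", label = NA)
)

setValidity("Recording", function(object) {
    msg <- character(0)
    if (length(object@sound) != length(object@ppg))
        msg <- c(msg, "sound and ppg must have identical length")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    if (length(object@sound) && !all(is.finite(object@sound)))
        msg <- c(msg, "sound values must be finite")
    if (length(object@ppg) && !all(is.finite(object@ppg)))
        msg <- c(msg, "ppg values must be finite")
    if (!object@side %in% c("left", "right", "unknown"))
        msg <- c(msg, "side must be 'left', 'right' or 'unknown'")
    if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param sound numeric vector of calibrated sound pressure (Pa).
#' @param ppg numeric vector of PPG samples (arbitrary units), same length.
#' @param fs sampling rate in Hz.
#' @param subject subject id string.
#' @param side ear side: `"left"`, `"right"` or `"unknown"`.
#' @param label optional logical ground-truth pulsatility annotation.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(sound = sin(2 * pi * 500 * (0:999) / 8000),
#'                  ppg = rep(0, 1000), fs = 8000)
#' duration(rec)
#' @export
Recording <- function(sound, ppg, fs, subject = "unknown",
                      side = "unknown", label = NA) {
    new("Recording", sound = as.numeric(sound), ppg = as.numeric(ppg),
        fs = as.numeric(fs), subject = as.character(subject),
        side = as.character(side), label = as.logical(label))
}

#' Calibration: microphone counts-to-pascal scale factor
#'
#' Maps raw WAV sample units ("counts") to sound pressure in pascals,
#' typically derived from a 1 kHz / 94 dB SPL calibrator tone.
#'
#' @slot countsPerPascal numeric(1), sample units per pascal; > 0.
#' @slot referenceNote character(1), free-text provenance (tone frequency,
#'   level, date).
#' @seealso [calibrateFromTone()], [readCalibration()]
#' @export
setClass("Calibration",
    representation(countsPerPascal = "numeric", referenceNote = "character"),
    prototype(referenceNote = "")
)

setValidity("Calibration", function(object) {
    if (length(object@countsPerPascal) != 1L ||
        !is.finite(object@countsPerPascal) || object@countsPerPascal <= 0)
        return("countsPerPascal must be a single positive finite number")
    TRUE
})

#' Construct a Calibration
#'
#' @param countsPerPascal sample units per pascal (> 0).
#' @param referenceNote free-text provenance note.
#' @return A [Calibration-class] object.
#' @export
Calibration <- function(countsPerPascal, referenceNote = "") {
    new("Calibration", countsPerPascal = as.numeric(countsPerPascal),
        referenceNote = as.character(referenceNote))
}

#' BeatSegmentation: beat-by-beat segmentation with artifact rejection
#'
#' Result of segmenting a sound recording at the PPG systolic peaks:
#' inter-peak segments, their RMS levels in dB SPL, and the keep/reject mask
#' from the median-plus-margin artifact rule.
#'
#' @slot peakIndices integer vector, sample indices (1-based) of systolic
#'   peaks, strictly increasing.
#' @slot segments integer matrix with columns `start`, `end`: half-open
#'   sample intervals `[start, end)` between consecutive peaks.
#' @slot segmentRmsDb numeric, per-segment sound RMS in dB SPL.
#' @slot keepMask logical, per-segment keep flag.
#' @slot rmsThresholdDb numeric(1), applied rejection threshold (dB SPL).
#' @slot marginDb numeric(1), margin added to the median RMS.
#' @seealso [segmentRecording()], [excise()]
#' @export
setClass("BeatSegmentation",
    representation(
        peakIndices    = "integer",
        segments       = "matrix",
        segmentRmsDb   = "numeric",
        keepMask       = "logical",
        rmsThresholdDb = "numeric",
        marginDb       = "numeric"
    )
)

setValidity("BeatSegmentation", function(object) {
    msg <- character(0)
    p <- object@peakIndices
    s <- object@segments
    if (length(p) && any(diff(p) <= 0))
        msg <- c(msg, "peakIndices must be strictly increasing")
    if (nrow(s) != max(0L, length(p) - 1L))
        msg <- c(msg, "number of segments must equal number of peaks - 1")
    if (nrow(s)) {
        if (any(s[, 2] <= s[, 1]))
            msg <- c(msg, "segments must be non-empty intervals")
        if (nrow(s) > 1L && any(s[-1L, 1] != s[-nrow(s), 2]))
            msg <- c(msg, "segments must be contiguous and ordered")
    }
    if (length(object@keepMask) != nrow(s) ||
        length(object@segmentRmsDb) != nrow(s))
        msg <- c(msg, "keepMask and segmentRmsDb must have one entry per segment")
    if (length(msg)) msg else TRUE
})

#' PTCIResult: per-band coherence indices for one recording
#'
#' Output of the detection algorithm: the estimated heart rate, the
#' magnitude-squared coherence spectrum between each octave-band sound
#' envelope and the PPG, the per-band PTCI (coherence at the heart rate) and
#' their maximum, the detector score PTCI_max.
#'
#' @slot heartRateHz numeric(1), estimated heart rate in Hz.
#' @slot bandPtci named numeric, PTCI per octave band (names are band
#'   centers in Hz).
#' @slot ptciMax numeric(1), maximum PTCI across bands.
#' @slot ptciMaxBandHz numeric(1), center frequency of the argmax band
#'   (ties broken toward the lowest center).
#' @slot coherence list of data.frames (`freq_hz`, `msc`), one per band.
#' @slot config list, the resolved analysis configuration.
#' @seealso [computePtci()]
#' @export
setClass("PTCIResult",
    representation(
        heartRateHz   = "numeric",
        bandPtci      = "numeric",
        ptciMax       = "numeric",
        ptciMaxBandHz = "numeric",
        coherence     = "list",
        config        = "list"
    )
)

setValidity("PTCIResult", function(object) {
    msg <- character(0)
    if (length(object@bandPtci) &&
        (any(object@bandPtci < -1e-9) || any(object@bandPtci > 1 + 1e-9)))
        msg <- c(msg, "bandPtci values must lie in [0, 1]")
    if (length(object@bandPtci) &&
        abs(object@ptciMax - max(object@bandPtci)) > 1e-12)
        msg <- c(msg, "ptciMax must equal max(bandPtci)")
    if (length(msg)) msg else TRUE
})
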