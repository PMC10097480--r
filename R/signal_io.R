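# WAV (RIFF) reading/writing and microphone calibration.
#
# Accepts PCM 16/24/32-bit and IEEE float32/float64 on read (the clinical
# hardware records 24-bit PCM); writes IEEE float32 by default so synthetic
# fixtures round-trip losslessly, with PCM 16/24 available.

REF_PRESSURE_PA <- 20e-6  # dB SPL reference, 20 micropascal

wav_read <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    riff <- readChar(con, 4L, useBytes = TRUE)
    if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
    invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
    wave <- readChar(con, 4L, useBytes = TRUE)
    if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

    fmt <- NULL; dat <- NULL
    repeat {
        id <- readChar(con, 4L, useBytes = TRUE)
        if (length(id) == 0L || nchar(id) < 4L) break
        size <- readBin(con, "integer", 1L, 4L, endian = "little")
        if (identical(id, "fmt ")) {
            raw <- readBin(con, "raw", size)
            u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
            u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
            fmt <- list(code = u16(0L), channels = u16(2L),
                        fs = u32(4L), bits = u16(14L))
            if (fmt$code == 65534L && size >= 40L)  # WAVE_FORMAT_EXTENSIBLE
                fmt$code <- u16(24L)
        } else if (identical(id, "data")) {
            dat <- readBin(con, "raw", size)
        } else {
            invisible(readBin(con, "raw", size))
        }
        if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # pad byte
        if (!is.null(fmt) && !is.null(dat)) break
    }
    if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk in ", path)

    n_bytes <- fmt$bits %/% 8L
    n_total <- length(dat) %/% n_bytes
    if (fmt$code == 3L) {
        x <- readBin(dat, "double", n_total, n_bytes, endian = "little")
    } else if (fmt$code == 1L && fmt$bits %in% c(16L, 32L)) {
        x <- readBin(dat, "integer", n_total, n_bytes,
                     signed = TRUE, endian = "little")
        x <- as.numeric(x)
    } else if (fmt$code == 1L && fmt$bits == 24L) {
        b <- matrix(as.integer(dat[seq_len(3L * n_total)]), nrow = 3L)
        x <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        x <- ifelse(x >= 8388608, x - 16777216, x)
    } else {
        stop(sprintf("unsupported WAV format (code %d, %d bit)",
                     fmt$code, fmt$bits))
    }
    n_frames <- n_total %/% fmt$channels
    data <- matrix(x[seq_len(n_frames * fmt$channels)],
                   ncol = fmt$channels, byrow = TRUE)
    list(data = data, fs = fmt$fs, bits = fmt$bits,
         float = fmt$code == 3L)
}

wav_write <- function(path, data, fs,
                      format = c("float32", "pcm16", "pcm24", "pcm32")) {
    format <- match.arg(format)
    if (is.vector(data)) data <- matrix(data, ncol = 1L)
    channels <- ncol(data)
    x <- as.numeric(t(data))              # interleave
    con <- file(path, "wb")
    on.exit(close(con))

    bits <- switch(format, float32 = 32L, pcm16 = 16L, pcm24 = 24L,
                   pcm32 = 32L)
    code <- if (format == "float32") 3L else 1L
    bytes_per <- bits %/% 8L
    data_size <- length(x) * bytes_per
    fmt_size <- if (code == 3L) 18L else 16L
    fact_size <- if (code == 3L) 12L else 0L
    riff_size <- 4L + (8L + fmt_size) + fact_size + (8L + data_size)

    w_u32 <- function(v) writeBin(as.integer(v), con, 4L, endian = "little")
    w_u16 <- function(v) writeBin(as.integer(v), con, 2L, endian = "little")
    writeChar("RIFF", con, eos = NULL); w_u32(riff_size)
    writeChar("WAVE", con, eos = NULL)
    writeChar("fmt ", con, eos = NULL); w_u32(fmt_size)
    w_u16(code); w_u16(channels); w_u32(fs)
    w_u32(fs * channels * bytes_per); w_u16(channels * bytes_per); w_u16(bits)
    if (code == 3L) {
        w_u16(0L)  # cbSize
        writeChar("fact", con, eos = NULL); w_u32(4L)
        w_u32(length(x) %/% channels)
    }
    writeChar("data", con, eos = NULL); w_u32(data_size)

    if (format == "float32") {
        writeBin(x, con, 4L, endian = "little")
    } else if (format == "pcm24") {
        v <- round(pmin(pmax(x, -8388608), 8388607))
        v <- ifelse(v < 0, v + 16777216, v)
        b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
        writeBin(as.raw(as.integer(b)), con)
    } else {
        lim <- 2^(bits - 1)
        v <- as.integer(round(pmin(pmax(x, -lim), lim - 1)))
        writeBin(v, con, bytes_per, endian = "little")
    }
    invisible(path)
}

#' Derive a calibration from a recorded calibrator tone
#'
#' Computes the counts-per-pascal scale factor from a recording of a
#' calibrator tone of known level (conventionally 1 kHz at 94 dB SPL):
#' `countsPerPascal = RMS(tone) / (20e-6 * 10^(level/20))`.
#'
#' @param toneSamples raw tone samples in WAV counts.
#' @param toneLevelDbSpl calibrator level in dB SPL (default 94).
#' @param referenceNote optional provenance note stored with the result.
#' @return A [Calibration-class] object.
#' @examples
#' tone <- sqrt(2) * sin(2 * pi * 1000 * (0:4409) / 44100)
#' calibrateFromTone(tone, 94)  # ~0.9976 counts/Pa
#' @export
calibrateFromTone <- function(toneSamples, toneLevelDbSpl = 94,
                              referenceNote = sprintf("tone at %g dB SPL",
                                                      toneLevelDbSpl)) {
    r <- sqrt(mean(toneSamples^2))
    if (!is.finite(r) || r <= 0)
        stop("calibration tone has zero RMS")
    Calibration(r / (REF_PRESSURE_PA * 10^(toneLevelDbSpl / 20)),
                referenceNote)
}

#' Sound pressure level of a pressure signal
#'
#' RMS level in dB SPL (re 20 uPa) over the full input. An all-zero input
#' yields `-Inf`, which downstream artifact-rejection arithmetic treats as
#' below any threshold.
#'
#' @param samples pressure samples in pascals.
#' @return level in dB SPL.
#' @examples
#' rmsDbSpl(rep(20e-6, 100))            # 0 dB SPL
#' rmsDbSpl(sin(2 * pi * (0:999) / 50)) # ~90.97 dB SPL
#' @export
rmsDbSpl <- function(samples) {
    if (!length(samples)) stop("empty input")
    r <- sqrt(mean(samples^2))
    if (r == 0) return(-Inf)
    20 * log10(r / REF_PRESSURE_PA)
}

#' Read a paired sound + PPG recording from WAV
#'
#' Reads either one stereo WAV (`soundChannel` = microphone,
#' `ppgChannel` = PPG) or two mono WAVs, converts the sound channel to
#' pascals with the supplied calibration, and checks that the two channels
#' were acquired synchronously (equal sampling rates; lengths differing by
#' at most one sample, in which case both are truncated to the common
#' length).
#'
#' @param soundPath WAV file with the microphone signal (or both channels).
#' @param ppgPath optional WAV file with the PPG; omit for a stereo file.
#' @param calibration a [Calibration-class] object.
#' @param soundChannel,ppgChannel channel indices within each file.
#' @param subject,side,label metadata stored in the [Recording-class].
#' @return A [Recording-class] with sound in Pa and PPG in raw units.
#' @export
readRecording <- function(soundPath, ppgPath = NULL, calibration,
                          soundChannel = 1L, ppgChannel = 2L,
                          subject = "unknown", side = "unknown",
                          label = NA) {
    stopifnot(is(calibration, "Calibration"))
    validObject(calibration)
    ws <- wav_read(soundPath)
    if (is.null(ppgPath)) {
        if (ncol(ws$data) < max(soundChannel, ppgChannel))
            stop("file has fewer channels than requested: ", soundPath)
        sound <- ws$data[, soundChannel]
        ppg <- ws$data[, ppgChannel]
        fs <- ws$fs
    } else {
        wp <- wav_read(ppgPath)
        if (ws$fs != wp$fs)
            stop(sprintf("sample rates differ: %g Hz (%s) vs %g Hz (%s)",
                         ws$fs, soundPath, wp$fs, ppgPath))
        sound <- ws$data[, soundChannel]
        ppg <- wp$data[, min(ppgChannel, ncol(wp$data))]
        if (abs(length(sound) - length(ppg)) > 1L)
            stop(sprintf(paste("channel lengths differ by %d samples;",
                               "acquisition was not synchronous"),
                         abs(length(sound) - length(ppg))))
        n <- min(length(sound), length(ppg))
        sound <- sound[seq_len(n)]
        ppg <- ppg[seq_len(n)]
        fs <- ws$fs
    }
    Recording(sound / calibration@countsPerPascal, ppg, fs,
              subject = subject, side = side, label = label)
}

#' Write a paired recording to WAV
#'
#' Inverse of [readRecording()]: sound is converted from pascals back to
#' counts with the calibration. With `ppgPath = NULL` a single stereo file
#' is written (channel 1 sound, channel 2 PPG), otherwise two mono files.
#'
#' @param rec a [Recording-class].
#' @param soundPath output WAV path.
#' @param ppgPath optional second WAV path for the PPG channel.
#' @param calibration a [Calibration-class] object.
#' @param format sample format; `"float32"` (default) round-trips the
#'   synthetic fixtures losslessly, `"pcm16"`/`"pcm24"`/`"pcm32"` quantize.
#' @return the sound path, invisibly.
#' @export
writeRecording <- function(rec, soundPath, ppgPath = NULL, calibration,
                           format = "float32") {
    stopifnot(is(rec, "Recording"), is(calibration, "Calibration"))
    counts <- rec@sound * calibration@countsPerPascal
    if (is.null(ppgPath)) {
        wav_write(soundPath, cbind(counts, rec@ppg), rec@fs, format)
    } else {
        wav_write(soundPath, counts, rec@fs, format)
        wav_write(ppgPath, rec@ppg, rec@fs, format)
    }
    invisible(soundPath)
}

#' Persist / load a calibration as JSON
#'
#' @param calibration a [Calibration-class].
#' @param path JSON file path.
#' @return `readCalibration` returns a [Calibration-class];
#'   `writeCalibration` the path, invisibly.
#' @export
writeCalibration <- function(calibration, path) {
    stopifnot(is(calibration, "Calibration"))
    jsonlite::write_json(
        list(counts_per_pascal = calibration@countsPerPascal,
             reference_note = calibration@referenceNote),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
    obj <- jsonlite::read_json(path)
    Calibration(as.numeric(obj$counts_per_pascal),
                as.character(obj$reference_note %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
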