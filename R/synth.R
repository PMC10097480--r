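# Synthetic paired sound + PPG recordings with full ground truth.
#
# Emulates the measurement conditions the detector targets: a
# quasi-periodic fingertip PPG (systolic peak plus dicrotic bump),
# band-limited microphone noise per octave band, a heartbeat-locked
# amplitude modulation confined to chosen bands (delayed 0.15 s after the
# PPG beat to mimic pulse-transit asynchrony), a slow breathing modulation
# as a confound, and optional high-RMS transient artifacts
# (swallowing/coughing analogues).

#' Synthetic-recording configuration
#'
#' All ground-truth parameters of one simulated recording. Defaults give a
#' 60 s non-pulsatile recording at 8 kHz: six octave-band noise carriers at
#' 30 dB SPL each, a 20 dB SPL broadband noise floor, heart rate 1.2 Hz
#' with 3% inter-beat jitter, and a mild breathing modulation (0.25 Hz,
#' depth 0.2). Setting any band's modulation depth above zero makes the
#' recording pulsatile.
#'
#' @param fs sampling rate in Hz (8000 keeps tests fast; 44100 supported).
#' @param durationS duration in seconds (>= 20 for coherence validity).
#' @param hrHz heart rate in Hz, within 0.8-2.
#' @param hrJitterFrac std of the inter-beat interval as a fraction of the
#'   mean interval (truncated at 3 sigma).
#' @param modDepth named numeric: heartbeat modulation depth in \[0, 1\]
#'   per octave-band center, e.g. `c("500" = 0.5)`; unnamed bands are 0.
#' @param carrierLevelDbSpl per-band carrier noise level in dB SPL
#'   (recycled across bands).
#' @param noiseFloorDbSpl broadband noise-floor level in dB SPL.
#' @param breathingHz,breathingDepth respiration-rate amplitude modulation
#'   applied to all carriers (a confound the detector must ignore).
#' @param artifacts data.frame with columns `time_s`, `duration_s`,
#'   `boost_db`: transient amplitude boosts (e.g. 20 dB swallowing bursts).
#' @param ppgNoiseSd PPG additive white-noise amplitude (default 0.01).
#' @param seed integer RNG seed; a fixed seed reproduces the recording
#'   bit-for-bit.
#' @return validated configuration list.
#' @export
synthConfig <- function(fs = 8000, durationS = 60, hrHz = 1.2,
                        hrJitterFrac = 0.03, modDepth = numeric(0),
                        carrierLevelDbSpl = 30, noiseFloorDbSpl = 20,
                        breathingHz = 0.25, breathingDepth = 0.2,
                        artifacts = NULL, ppgNoiseSd = 0.01, seed = 1) {
    centers <- c(125, 250, 500, 1000, 2000, 4000)
    depth <- stats::setNames(numeric(length(centers)),
                             as.character(centers))
    if (length(modDepth)) {
        if (is.null(names(modDepth)))
            stop("modDepth must be named by band center, e.g. c('500' = 0.5)")
        bad <- setdiff(names(modDepth), names(depth))
        if (length(bad))
            stop("unknown band center(s): ", paste(bad, collapse = ", "))
        depth[names(modDepth)] <- modDepth
    }
    if (any(depth < 0 | depth > 1))
        stop("modulation depths must lie in [0, 1]")
    if (durationS < 20)
        stop("duration must be at least 20 s for a valid coherence estimate")
    if (hrHz < 0.8 || hrHz > 2)
        stop("heart rate must lie in 0.8-2 Hz")
    if (!is.null(artifacts)) {
        stopifnot(all(c("time_s", "duration_s", "boost_db") %in%
                          names(artifacts)))
        if (any(artifacts$time_s < 0 |
                artifacts$time_s + artifacts$duration_s > durationS))
            stop("artifact intervals must lie within the recording")
    }
    list(fs = fs, durationS = durationS, hrHz = hrHz,
         hrJitterFrac = hrJitterFrac, modDepth = depth,
         carrierLevelDbSpl = rep_len(carrierLevelDbSpl, length(centers)),
         noiseFloorDbSpl = noiseFloorDbSpl, breathingHz = breathingHz,
         breathingDepth = breathingDepth, artifacts = artifacts,
         ppgNoiseSd = ppgNoiseSd, seed = as.integer(seed))
}

#' Generate ground-truth beat times
#'
#' `t[i+1] = t[i] + (1/hr) * (1 + jitter_i)` with zero-mean Gaussian jitter
#' of std `hrJitterFrac`, truncated at 3 sigma; the first beat falls at
#' 0.4 s.
#'
#' @param config a [synthConfig()] list.
#' @return beat times in seconds, all within the recording.
#' @export
genBeatTimes <- function(config) {
    set.seed(config$seed)
    ibi <- 1 / config$hrHz
    t <- 0.4
    times <- numeric(0)
    while (t < config$durationS) {
        times <- c(times, t)
        j <- stats::rnorm(1, 0, config$hrJitterFrac)
        j <- max(-3 * config$hrJitterFrac,
                 min(3 * config$hrJitterFrac, j))
        t <- t + ibi * (1 + j)
    }
    times
}

#' Generate a synthetic PPG
#'
#' Per beat, a systolic Gaussian pulse (amplitude 1, width 0.08 x the beat
#' interval) plus a dicrotic bump (amplitude 0.3, offset 0.25 x interval,
#' width 0.12 x interval), with additive white noise. The global maximum
#' within each beat falls on the systolic pulse, the ground truth for peak
#' detection.
#'
#' @param beatTimes beat times in seconds, from [genBeatTimes()].
#' @param config a [synthConfig()] list.
#' @return PPG samples (arbitrary units), `round(durationS * fs)` long.
#' @export
genPpg <- function(beatTimes, config) {
    set.seed(config$seed + 1L)
    n <- round(config$durationS * config$fs)
    fs <- config$fs
    ppg <- stats::rnorm(n, 0, config$ppgNoiseSd)
    nb <- length(beatTimes)
    if (nb == 0L) return(ppg)
    ibis <- if (nb > 1L) diff(beatTimes) else 1 / config$hrHz
    ibis <- c(ibis, ibis[length(ibis)])     # last beat reuses previous IBI
    add_gauss <- function(center_s, amp, width_s) {
        lo <- max(1L, floor((center_s - 4 * width_s) * fs) + 1L)
        hi <- min(n, ceiling((center_s + 4 * width_s) * fs) + 1L)
        if (lo > hi) return(invisible())
        t <- (lo:hi - 1) / fs
        ppg[lo:hi] <<- ppg[lo:hi] + amp * exp(-(t - center_s)^2 /
                                                  (2 * width_s^2))
    }
    for (i in seq_len(nb)) {
        add_gauss(beatTimes[i], 1.0, 0.08 * ibis[i])
        add_gauss(beatTimes[i] + 0.25 * ibis[i], 0.3, 0.12 * ibis[i])
    }
    ppg
}

#' Generate a synthetic ear-canal sound
#'
#' Sum over octave bands of band-passed white noise scaled to the
#' configured carrier level and amplitude-modulated by
#' `1 + m_b * g(t)`, where `g` is a raised-cosine pulse of width 0.3 x the
#' beat interval centered 0.15 s after each beat time (the pulse-transit
#' delay). A breathing term `1 + depth * sin(2 pi f_breath t)` multiplies
#' all carriers, a broadband noise floor is added, and artifact intervals
#' multiply the summed signal by `10^(boost_db/20)`.
#'
#' @param beatTimes beat times in seconds.
#' @param config a [synthConfig()] list.
#' @return sound pressure samples in Pa.
#' @export
genSound <- function(beatTimes, config) {
    set.seed(config$seed + 2L)
    n <- round(config$durationS * config$fs)
    fs <- config$fs
    t <- (seq_len(n) - 1) / fs

    # heartbeat pulse waveform shared by all modulated bands
    g <- numeric(n)
    nb <- length(beatTimes)
    if (nb) {
        ibis <- if (nb > 1L) diff(beatTimes) else 1 / config$hrHz
        ibis <- c(ibis, ibis[length(ibis)])
        for (i in seq_len(nb)) {
            w <- 0.3 * ibis[i]
            c_s <- beatTimes[i] + 0.15
            lo <- max(1L, floor((c_s - w / 2) * fs) + 1L)
            hi <- min(n, ceiling((c_s + w / 2) * fs) + 1L)
            if (lo > hi) next
            tt <- (lo:hi - 1) / fs
            seg <- 0.5 * (1 + cos(2 * pi * (tt - c_s) / w))
            seg[abs(tt - c_s) > w / 2] <- 0
            g[lo:hi] <- pmax(g[lo:hi], seg)
        }
    }
    breathing <- 1 + config$breathingDepth *
        sin(2 * pi * config$breathingHz * t)

    bands <- suppressWarnings(octaveBands(fs = fs))
    sound <- numeric(n)
    for (i in seq_len(nrow(bands))) {
        carrier <- bandpassOctave(stats::rnorm(n), bands[i, ], fs)
        target <- REF_PRESSURE_PA * 10^(config$carrierLevelDbSpl[i] / 20)
        carrier <- carrier * target / sqrt(mean(carrier^2))
        m <- config$modDepth[[as.character(bands$center_hz[i])]]
        sound <- sound + carrier * (1 + m * g) * breathing
    }
    floor_rms <- REF_PRESSURE_PA * 10^(config$noiseFloorDbSpl / 20)
    sound <- sound + stats::rnorm(n, 0, floor_rms)

    if (!is.null(config$artifacts)) {
        for (r in seq_len(nrow(config$artifacts))) {
            a <- config$artifacts[r, ]
            lo <- floor(a$time_s * fs) + 1L
            hi <- min(n, ceiling((a$time_s + a$duration_s) * fs))
            sound[lo:hi] <- sound[lo:hi] * 10^(a$boost_db / 20)
        }
    }
    sound
}

#' Generate a complete synthetic recording with ground truth
#'
#' Composes [genBeatTimes()], [genPpg()] and [genSound()]; the
#' [Recording-class] carries `label = TRUE` iff any band has a positive
#' modulation depth.
#'
#' @param config a [synthConfig()] list.
#' @return list with `recording` (a [Recording-class]) and `truth`
#'   (beat times, `isPulsatile`, per-band depths, artifact table).
#' @export
genRecording <- function(config = synthConfig()) {
    beats <- genBeatTimes(config)
    ppg <- genPpg(beats, config)
    sound <- genSound(beats, config)
    pulsatile <- any(config$modDepth > 0)
    list(recording = Recording(sound, ppg, config$fs,
                               subject = sprintf("synth-seed%d", config$seed),
                               label = pulsatile),
         truth = list(beatTimes = beats, isPulsatile = pulsatile,
                      modDepth = config$modDepth,
                      artifacts = config$artifacts))
}

#' Generate a labelled synthetic cohort
#'
#' `nPos` pulsatile and `nNeg` non-pulsatile recording configurations with
#' per-recording heart rate drawn uniformly in 0.9-1.8 Hz and per-recording
#' seeds derived deterministically from the master seed. Each positive
#' recording is modulated (depth `posDepth`) in one octave band drawn
#' uniformly from the six centers. Configurations (not samples) are
#' returned so that cohorts of any size stay cheap; generate each recording
#' on demand with [genRecording()].
#'
#' @param nPos,nNeg number of pulsatile / non-pulsatile members (>= 1).
#' @param baseConfig a [synthConfig()] list supplying all other settings.
#' @param seed master seed for the cohort.
#' @param posDepth modulation depth of the pulsatile members (default 0.5).
#' @return list with `configs` (list of [synthConfig()] lists) and
#'   `manifest` (data.frame: `recording_id`, `label`, `hr_hz`,
#'   `mod_band_hz`, `mod_depth`, `seed`).
#' @export
genCohort <- function(nPos, nNeg, baseConfig = synthConfig(), seed = 1,
                      posDepth = 0.5) {
    stopifnot(nPos >= 1, nNeg >= 1)
    n <- nPos + nNeg
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    hrs <- stats::runif(n, 0.9, 1.8)
    bands_pos <- sample(c(125, 250, 500, 1000, 2000, 4000), nPos,
                        replace = TRUE)
    configs <- vector("list", n)
    label <- rep(c(TRUE, FALSE), c(nPos, nNeg))
    band <- c(bands_pos, rep(NA_real_, nNeg))
    for (i in seq_len(n)) {
        cfg <- baseConfig
        cfg$hrHz <- hrs[i]
        cfg$seed <- seeds[i]
        cfg$modDepth[] <- 0
        if (label[i]) cfg$modDepth[as.character(band[i])] <- posDepth
        configs[[i]] <- cfg
    }
    list(configs = configs,
         manifest = data.frame(
             recording_id = sprintf("S%03d", seq_len(n)),
             label = label, hr_hz = hrs, mod_band_hz = band,
             mod_depth = ifelse(label, posDepth, 0), seed = seeds))
}
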