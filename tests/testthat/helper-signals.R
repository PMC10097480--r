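# shared helpers: sinusoid-regression amplitude measurement and a
# central-window extractor (filter edges are excluded from assertions)

central <- function(x, frac = 0.8) {
    n <- length(x)
    drop <- floor(n * (1 - frac) / 2)
    x[(drop + 1):(n - drop)]
}

# amplitude of the f-Hz component of x by least-squares sinusoid regression
sine_amplitude <- function(x, fs, f) {
    t <- (seq_along(x) - 1) / fs
    fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
    sqrt(sum(stats::coef(fit)[2:3]^2))
}

sinusoid <- function(f, fs, dur, amp = 1, phase = 0) {
    amp * sin(2 * pi * f * (0:(round(dur * fs) - 1)) / fs + phase)
}

# quick clean pulsatile/null recording for pipeline tests
quick_recording <- function(seed, depth = 0, band = "500", dur = 30,
                            ...) {
    md <- if (depth > 0) stats::setNames(depth, band) else numeric(0)
    genRecording(synthConfig(durationS = dur, modDepth = md, seed = seed,
                             ...))
}

quiet_ptci <- function(rec, ...) suppressWarnings(computePtci(rec, ...))
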