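# independent brute-force coherence: explicit segment loop, naive DFT,
# accumulated cross/auto spectra
naive_msc <- function(x, y, rate, window_s = 6, overlap_s = 3) {
    L <- round(window_s * rate)
    hop <- L - round(overlap_s * rate)
    w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hamming
    nf <- L %/% 2 + 1
    dft <- exp(-2i * pi * outer(0:(nf - 1), 0:(L - 1)) / L)
    sxx <- syy <- numeric(nf); sxy <- complex(nf)
    for (s in seq(1, length(x) - L + 1, by = hop)) {
        xs <- dft %*% (w * x[s:(s + L - 1)])
        ys <- dft %*% (w * y[s:(s + L - 1)])
        sxx <- sxx + Mod(xs)^2
        syy <- syy + Mod(ys)^2
        sxy <- sxy + xs * Conj(ys)
    }
    as.numeric(Mod(sxy)^2 / (sxx * syy))
}

test_that("Welch coherence is exact self-coherence and matches the naive DFT oracle", {
    set.seed(51)
    rate <- 100
    x <- rnorm(20 * rate); y <- rnorm(20 * rate)

    self <- mscWelch(x, x, rate)
    expect_true(all(abs(self$msc - 1) < 1e-10))

    got <- mscWelch(x, y, rate)
    expect_equal(got$msc, naive_msc(x, y, rate), tolerance = 1e-8)
    expect_equal(got$freq_hz, (0:(nrow(got) - 1)) / 6)

    expect_error(mscWelch(x, y[-1], rate), "equal length")
    expect_error(mscWelch(x[1:100], y[1:100], rate), "shorter than one")
    expect_warning(mscWelch(x[1:700], y[1:700], rate), "fewer than 3")
})

test_that("coherence of independent noise stays near the estimator bias", {
    set.seed(52)
    rate <- 100
    x <- rnorm(120 * rate); y <- rnorm(120 * rate)
    m <- mean(mscWelch(x, y, rate)$msc)
    expect_gt(m, 0)
    expect_lt(m, 0.15)
})

test_that("coherence magnitude is invariant to a pure delay", {
    set.seed(53)
    rate <- 100
    x <- as.numeric(sosFiltFilt(butterworthSos(4, 10, rate, "low"),
                                rnorm(60 * rate)))
    y <- c(tail(x, 0.5 * rate), head(x, -0.5 * rate))  # circular 0.5 s delay
    m <- mscWelch(x, y, rate)
    powered <- m$freq_hz > 0.2 & m$freq_hz < 5
    # finite windows leak: a delay of d shifts d/window (= 8% here) of each
    # segment's content, costing ~2 d/window in coherence at the worst bins
    # (an identical floor is observed with an independent Welch coherence
    # implementation); far from the 1/K independent-noise bias nonetheless
    expect_gt(min(m$msc[powered]), 0.85)
    expect_gt(mean(m$msc[powered]), 0.90)
})

test_that("the PTCI search window selects exactly the bins near the heart rate", {
    freqs <- (0:60) / 6
    # hr = 1.25 Hz, halfwidth 0.15: only the 1.1667 and 1.3333 Hz bins
    msc <- rep(0.9, 61)
    msc[abs(freqs - 7 / 6) < 1e-9] <- 0.3
    msc[abs(freqs - 8 / 6) < 1e-9] <- 0.7
    coh <- data.frame(freq_hz = freqs, msc = msc)
    expect_equal(ptciAtHeartRate(coh, 1.25, 0.15), 0.7)

    expect_equal(ptciAtHeartRate(data.frame(freq_hz = freqs,
                                            msc = rep(1, 61)), 1.2), 1)
    m0 <- rep(0, 61); m0[which.min(abs(freqs - 1.2))] <- 0.8
    expect_equal(ptciAtHeartRate(data.frame(freq_hz = freqs, msc = m0),
                                 1.2), 0.8)
    expect_error(ptciAtHeartRate(coh, 1.25, halfwidthHz = 1e-6), "no coherence bins")
})

test_that("heart-rate estimation finds the spectral peak in 0.8-2 Hz", {
    fs <- 100
    expect_equal(estimateHeartRate(sinusoid(1.2, fs, 60), fs), 1.2,
                 tolerance = 1 / 60)
    # white noise: a value is returned (contract: no error, PTCI stays low)
    set.seed(54)
    hr <- estimateHeartRate(rnorm(60 * fs), fs)
    expect_gte(hr, 0.8); expect_lte(hr, 2)
    expect_error(estimateHeartRate(sinusoid(1.2, fs, 5), fs), "shorter")
})

test_that("a band-confined heartbeat modulation drives PTCI in that band", {
    gen <- quick_recording(seed = 61, depth = 0.5, band = "500", dur = 60)
    res <- quiet_ptci(gen$recording)
    expect_gte(ptciMax(res), 0.9)
    expect_equal(res@ptciMaxBandHz, 500)
    expect_true(all(bandPtci(res) >= 0 & bandPtci(res) <= 1))
    expect_equal(ptciMax(res), max(bandPtci(res)))
    expect_equal(heartRateHz(res), 1.2, tolerance = 0.05)
})

test_that("PTCI is invariant to positive rescaling of either channel", {
    gen <- quick_recording(seed = 62, depth = 0.25, dur = 40)
    rec <- gen$recording
    ref <- quiet_ptci(rec)
    scaled <- Recording(3.7 * soundPa(rec), 0.21 * ppgSignal(rec),
                        sampleRate(rec))
    got <- quiet_ptci(scaled)
    expect_equal(bandPtci(got), bandPtci(ref), tolerance = 0.02)
    expect_equal(ptciMax(got), ptciMax(ref), tolerance = 0.02)
})

test_that("coherence shows harmonic structure: stronger at 2x the heart rate", {
    gen <- quick_recording(seed = 63, depth = 0.8, dur = 60,
                           noiseFloorDbSpl = 0)
    res <- quiet_ptci(gen$recording)
    hr <- heartRateHz(res)
    coh <- res@coherence[["500"]]
    msc_at <- function(f) max(coh$msc[abs(coh$freq_hz - f) <= 0.15])
    expect_gt(msc_at(2 * hr), msc_at(1.5 * hr))
})

test_that("octave bands halve and double around their centers, clipped at Nyquist", {
    b <- octaveBands()
    expect_equal(b$low_hz, b$center_hz / sqrt(2))
    expect_equal(b$high_hz, b$center_hz * sqrt(2))
    expect_warning(b8 <- octaveBands(fs = 8000), "clipping")
    expect_equal(b8$high_hz[b8$center_hz == 4000], 3900)
    expect_false(any(b8$clipped[-nrow(b8)]))
    expect_warning(expect_warning(octaveBands(fs = 4000), "dropping"),
                   "clipping")
})
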