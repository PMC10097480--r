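test_that("PPG low-pass passes the pulse band and kills mains-range noise", {
    fs <- 1000
    expect_equal(central(lowpassPpg(rep(1, 10 * fs), fs)),
                 central(rep(1, 10 * fs)), tolerance = 1e-6)

    x1 <- sinusoid(1, fs, 20)
    expect_equal(sine_amplitude(central(lowpassPpg(x1, fs)), fs, 1), 1,
                 tolerance = 0.01)

    mix <- x1 + sinusoid(50, fs, 20)
    resid <- sine_amplitude(central(lowpassPpg(mix, fs)), fs, 50)
    expect_lt(20 * log10(resid), -40)

    expect_error(lowpassPpg(x1, fs = 8, cutoff = 5), "Nyquist")
})

test_that("systolic peaks of a pure pulse rhythm land one beat apart", {
    fs <- 100
    x <- sinusoid(1.2, fs, 60)
    peaks <- detectSystolicPeaks(x, fs)
    expect_true(length(peaks) %in% c(71L, 72L))
    expect_true(all(abs(diff(peaks) - fs / 1.2) <= 1))

    expect_error(detectSystolicPeaks(rep(1, 60 * fs), fs), "peak")
    expect_error(detectSystolicPeaks(sinusoid(1.2, fs, 5), fs),
                 "shorter than 10 s")
})

test_that("peak detection recovers synthetic beats at 72 bpm with jitter", {
    cfg <- synthConfig(fs = 500, durationS = 60, hrHz = 1.2,
                       hrJitterFrac = 0.03, seed = 21)
    beats <- genBeatTimes(cfg)
    ppg <- genPpg(beats, cfg)
    peaks <- detectSystolicPeaks(lowpassPpg(ppg, cfg$fs), cfg$fs)
    got <- (peaks - 1) / cfg$fs
    # median inter-beat interval within 2% of ground truth
    expect_equal(median(diff(got)), median(diff(beats)), tolerance = 0.02)
    # >= 95% of true beats matched within 50 ms
    hit <- vapply(beats, function(b) any(abs(got - b) < 0.05), logical(1))
    expect_gte(mean(hit), 0.95)
})

test_that("segmentation forms contiguous half-open inter-peak intervals", {
    s <- segmentByBeats(c(100, 200, 300), 1000)
    expect_identical(s, cbind(start = c(100L, 200L), end = c(200L, 300L)))
    expect_identical(nrow(segmentByBeats(c(5, 50), 100)), 1L)
    expect_error(segmentByBeats(100, 1000), "at least 2")
    expect_error(segmentByBeats(c(200, 100), 1000), "increasing")

    fs <- 100
    peaks <- detectSystolicPeaks(sinusoid(1.2, fs, 60), fs)
    expect_identical(nrow(segmentByBeats(peaks, 60 * fs)),
                     length(peaks) - 1L)
})

test_that("artifact rejection applies the median + margin rule, keeping ties", {
    r <- rejectArtifacts(c(60, 60, 60, 80), marginDb = 6)
    expect_identical(r$keepMask, c(TRUE, TRUE, TRUE, FALSE))
    expect_equal(r$thresholdDb, 66)

    # the literal exceeds-the-median rule (margin 0) halves clean data
    r0 <- rejectArtifacts(c(60, 61, 62, 63), marginDb = 0)
    expect_identical(r0$keepMask, c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(r0$thresholdDb, 61.5)

    # all-equal RMS: nothing exceeds the median at any margin >= 0
    expect_true(all(rejectArtifacts(rep(55, 7), 0)$keepMask))

    # invariance under a constant level shift
    set.seed(31)
    rms <- rnorm(25, 60, 4)
    expect_identical(rejectArtifacts(rms, 3)$keepMask,
                     rejectArtifacts(rms + 17.3, 3)$keepMask)

    # -Inf (silent segment) is below any threshold
    expect_true(rejectArtifacts(c(-Inf, 60, 60), 0)$keepMask[1])
    expect_error(rejectArtifacts(numeric(0)), "no segments")
})

test_that("excision keeps alignment and reduces to the inter-peak span", {
    set.seed(32)
    fs <- 100
    rec <- Recording(rnorm(1000, 0, 0.01), rnorm(1000), fs)
    segs <- cbind(start = c(101L, 201L, 301L), end = c(201L, 301L, 401L))
    mkseg <- function(keep) new("BeatSegmentation",
        peakIndices = c(101L, 201L, 301L, 401L), segments = segs,
        segmentRmsDb = rep(60, 3), keepMask = keep,
        rmsThresholdDb = Inf, marginDb = Inf)

    all_kept <- excise(rec, mkseg(rep(TRUE, 3)))
    expect_identical(soundPa(all_kept), soundPa(rec)[101:400])
    expect_identical(ppgSignal(all_kept), ppgSignal(rec)[101:400])

    some <- excise(rec, mkseg(c(TRUE, FALSE, TRUE)))
    expect_length(soundPa(some), 200L)
    expect_identical(soundPa(some), soundPa(rec)[c(101:200, 301:400)])
    expect_identical(ppgSignal(some), ppgSignal(rec)[c(101:200, 301:400)])

    expect_error(excise(rec, mkseg(rep(FALSE, 3))), "no segments survive")
})

test_that("injected loud bursts are rejected while clean beats survive", {
    art <- data.frame(time_s = c(8, 17), duration_s = 0.3, boost_db = 20)
    gen <- genRecording(synthConfig(durationS = 30, artifacts = art,
                                    seed = 41))
    rec <- gen$recording
    seg <- segmentRecording(rec, marginDb = 6)
    tab <- segmentationTable(seg, sampleRate(rec))
    # a segment "bears" a burst when a material share of it overlaps; a
    # boundary sliver (a few ms of a 0.3 s burst) carries too little boosted
    # energy to stand above the beat-to-beat RMS spread
    overlap_s <- mapply(function(s, e)
        sum(pmax(0, pmin(e, art$time_s + art$duration_s) -
                     pmax(s, art$time_s))),
        tab$start_s, tab$end_s)
    expect_true(all(!tab$kept[overlap_s >= 0.1]))
    # every burst knocks out at least one segment
    for (a in art$time_s)
        expect_true(any(!tab$kept[tab$start_s < a + 0.3 & tab$end_s > a]))
    expect_lt(mean(!tab$kept[overlap_s == 0]), 0.10)

    # unbounded margin keeps everything: excision = inter-peak restriction
    seg_inf <- segmentRecording(rec, marginDb = Inf)
    clean <- excise(rec, seg_inf)
    p <- peakIndices(seg_inf)
    expect_identical(soundPa(clean),
                     soundPa(rec)[p[1]:(p[length(p)] - 1L)])
})
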