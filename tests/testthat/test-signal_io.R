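test_that("calibration from a tone matches the analytic scale factor", {
    fs <- 44100
    tone <- sinusoid(1000, fs, 1, amp = sqrt(2))
    # 94 dB SPL corresponds to 1.00237 Pa RMS, so a unit-RMS tone gives
    # counts_per_pascal = 1 / 1.00237
    cal <- calibrateFromTone(tone, 94)
    expect_equal(cal@countsPerPascal, 1 / (20e-6 * 10^(94 / 20)),
                 tolerance = 1e-6)
    expect_equal(cal@countsPerPascal, 0.99763, tolerance = 1e-4)

    # reference level: a tone whose RMS is exactly 20 uPa at 0 dB SPL
    cal0 <- calibrateFromTone(sinusoid(1000, fs, 1, amp = sqrt(2) * 20e-6), 0)
    expect_equal(cal0@countsPerPascal, 1.0, tolerance = 1e-9)

    # linearity in the tone amplitude
    for (k in c(0.25, 2, 37.5)) {
        calk <- calibrateFromTone(k * tone, 94)
        expect_equal(calk@countsPerPascal, k * cal@countsPerPascal,
                     tolerance = 1e-12)
    }
    expect_error(calibrateFromTone(numeric(100), 94), "zero RMS")
})

test_that("rmsDbSpl reproduces reference levels and dB arithmetic", {
    expect_equal(rmsDbSpl(rep(20e-6, 100)), 0)
    expect_equal(rmsDbSpl(sinusoid(50, 1000, 1)),
                 20 * log10((1 / sqrt(2)) / 20e-6), tolerance = 1e-9)
    expect_equal(rmsDbSpl(sinusoid(50, 1000, 1)), 90.969, tolerance = 1e-3)
    # the 94 dB SPL calibrator tone (1.00237 Pa RMS)
    expect_equal(rmsDbSpl(sinusoid(1000, 44100, 1, amp = 1.41774)), 94.0,
                 tolerance = 1e-2)

    x <- rnorm(1000)
    expect_identical(rmsDbSpl(x), rmsDbSpl(-x))
    expect_identical(rmsDbSpl(x), rmsDbSpl(rev(x)))
    expect_equal(rmsDbSpl(2 * x) - rmsDbSpl(x), 20 * log10(2),
                 tolerance = 1e-9)
    expect_identical(rmsDbSpl(numeric(10)), -Inf)
    expect_error(rmsDbSpl(numeric(0)), "empty")
})

test_that("recordings round-trip through stereo and mono WAV layouts", {
    set.seed(11)
    fs <- 8000
    rec <- Recording(sound = rnorm(fs, 0, 0.02), ppg = rnorm(fs), fs = fs,
                     subject = "rt", side = "left")
    cal <- Calibration(1e5, "unit test")

    stereo <- tempfile(fileext = ".wav")
    writeRecording(rec, stereo, calibration = cal)
    back <- readRecording(stereo, calibration = cal, subject = "rt",
                          side = "left")
    # float32 quantization: ~7 significant digits
    expect_equal(soundPa(back), soundPa(rec), tolerance = 1e-6)
    expect_equal(ppgSignal(back), ppgSignal(rec), tolerance = 1e-6)
    expect_equal(sampleRate(back), fs)

    spath <- tempfile(fileext = ".wav"); ppath <- tempfile(fileext = ".wav")
    writeRecording(rec, spath, ppath, calibration = cal)
    back2 <- readRecording(spath, ppath, cal)
    expect_equal(soundPa(back2), soundPa(rec), tolerance = 1e-6)
    expect_equal(ppgSignal(back2), ppgSignal(rec), tolerance = 1e-6)
})

test_that("24-bit PCM reads back within one quantization step", {
    set.seed(12)
    fs <- 8000
    # counts up to ~1e6 so the 24-bit step (1 count) is ~1e-6 Pa here
    rec <- Recording(sound = rnorm(fs, 0, 0.05),
                     ppg = round(rnorm(fs, 0, 2e5)), fs = fs)
    cal <- Calibration(1e6)
    p <- tempfile(fileext = ".wav")
    writeRecording(rec, p, calibration = cal, format = "pcm24")
    back <- readRecording(p, calibration = cal)
    expect_lt(max(abs(soundPa(back) - soundPa(rec))), 1 / cal@countsPerPascal)
    expect_identical(ppgSignal(back), ppgSignal(rec))  # integer PPG: exact
})

test_that("desynchronized channel pairs are refused, 1-sample slack trimmed", {
    fs <- 1000
    cal <- Calibration(1)
    s1 <- tempfile(fileext = ".wav"); s2 <- tempfile(fileext = ".wav")
    ptcoherence:::wav_write(s1, rnorm(fs), fs)
    ptcoherence:::wav_write(s2, rnorm(fs + 1), fs)
    rec <- readRecording(s1, s2, cal)
    expect_length(soundPa(rec), fs)

    s3 <- tempfile(fileext = ".wav")
    ptcoherence:::wav_write(s3, rnorm(fs + 5), fs)
    expect_error(readRecording(s1, s3, cal), "lengths differ")

    s4 <- tempfile(fileext = ".wav")
    ptcoherence:::wav_write(s4, rnorm(fs), 2 * fs)
    expect_error(readRecording(s1, s4, cal), "rates differ")
})

test_that("calibration persists as JSON", {
    cal <- calibrateFromTone(sinusoid(1000, 44100, 0.5, amp = 3), 94,
                             "bench calibrator")
    p <- tempfile(fileext = ".json")
    writeCalibration(cal, p)
    back <- readCalibration(p)
    expect_equal(back@countsPerPascal, cal@countsPerPascal,
                 tolerance = 1e-12)
    expect_identical(back@referenceNote, "bench calibrator")
})

test_that("Recording validity catches malformed inputs", {
    expect_error(Recording(1:10, 1:9, 100), "identical length")
    expect_error(Recording(c(1, NA), c(1, 2), 100), "finite")
    expect_error(Recording(1:2, 1:2, -5), "positive")
    rec <- Recording(1:4 / 10, 4:1, 2)
    expect_equal(duration(rec), 2)
})
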