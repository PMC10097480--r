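# Zero-phase IIR filtering on second-order sections.
#
# Narrow octave bands at audio rates (e.g. the 125 Hz band at 44.1 kHz) are
# numerically hopeless in expanded transfer-function (b, a) form: the pole
# polynomial is ill-conditioned and filtfilt on it overflows. All filtering
# here therefore designs Butterworth filters analytically in zero-pole-gain
# form and runs them as cascaded biquads.

#' Design a digital Butterworth filter as second-order sections
#'
#' Analog Butterworth prototype -> frequency transform -> bilinear transform
#' -> conjugate-pair biquad sections, with the passband gain normalised
#' numerically at a reference frequency (DC for low-pass, Nyquist for
#' high-pass, the geometric band center for band-pass).
#'
#' @param order filter order (the analog prototype order; a band-pass of
#'   order n has 2n poles).
#' @param cutoff cutoff frequency in Hz (length 1 for `"low"`/`"high"`,
#'   length 2 `c(low, high)` for `"pass"`).
#' @param fs sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return numeric matrix with one row per biquad and columns
#'   `b0 b1 b2 a0 a1 a2` (`a0` always 1).
#' @examples
#' sos <- butterworthSos(5, 5, fs = 8000, type = "low")
#' nrow(sos)  # 3 sections for a 5th-order filter
#' @export
butterworthSos <- function(order, cutoff, fs,
                           type = c("low", "high", "pass")) {
    type <- match.arg(type)
    stopifnot(order >= 1, fs > 0, all(cutoff > 0))
    if (any(cutoff >= fs / 2))
        stop("cutoff frequency must be below the Nyquist frequency (fs/2)")
    if (type == "pass") {
        if (length(cutoff) != 2L || cutoff[1] >= cutoff[2])
            stop("band-pass requires cutoff = c(low, high) with low < high")
    } else if (length(cutoff) != 1L) {
        stop("low/high-pass require a single cutoff frequency")
    }

    warp <- function(f) 2 * fs * tan(pi * f / fs)
    k <- seq_len(order)
    proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles

    if (type == "low") {
        wc <- warp(cutoff)
        poles <- proto * wc
        n_zero_pos <- 0L                  # digital zeros at z = +1
        n_zero_neg <- order               # digital zeros at z = -1
        f_ref <- 0
    } else if (type == "high") {
        wc <- warp(cutoff)
        poles <- wc / proto
        n_zero_pos <- order
        n_zero_neg <- 0L
        f_ref <- fs / 2
    } else {
        wl <- warp(cutoff[1]); wh <- warp(cutoff[2])
        bw <- wh - wl; w0 <- sqrt(wl * wh)
        q <- proto * bw / 2
        disc <- sqrt(q^2 - w0^2)
        poles <- c(q + disc, q - disc)
        n_zero_pos <- order
        n_zero_neg <- order
        # reference: the digital frequency whose prewarped image is w0
        f_ref <- fs / pi * atan(w0 / (2 * fs))
    }

    zp <- (2 * fs + poles) / (2 * fs - poles)   # bilinear transform
    if (any(Mod(zp) >= 1))
        stop("designed filter is unstable; check order and cutoff")

    # split into conjugate pairs / real poles
    tol <- 1e-8 * max(Mod(zp))
    is_real <- abs(Im(zp)) < tol
    reals <- sort(Re(zp[is_real]))
    upper <- zp[!is_real & Im(zp) > 0]
    upper <- upper[order(Mod(upper))]          # least-peaked sections first

    sections <- list()
    for (p in upper)
        sections[[length(sections) + 1L]] <-
            c(1, -2 * Re(p), Mod(p)^2)
    while (length(reals) >= 2L) {
        sections[[length(sections) + 1L]] <-
            c(1, -(reals[1] + reals[2]), reals[1] * reals[2])
        reals <- reals[-(1:2)]
    }
    if (length(reals) == 1L)
        sections[[length(sections) + 1L]] <- c(1, -reals[1], 0)

    n_sec <- length(sections)
    sos <- matrix(0, n_sec, 6L,
                  dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
    np <- n_zero_pos; nn <- n_zero_neg
    for (s in seq_len(n_sec)) {
        sos[s, 4:6] <- sections[[s]]
        single <- sections[[s]][3] == 0 && s == n_sec && (np + nn) %% 2L == 1L
        # distribute zeros: band-pass gets one +1 and one -1 per section,
        # low/high-pass get a like pair (or a single zero for the odd section)
        if (single) {
            if (np > 0) { sos[s, 1:3] <- c(1, -1, 0); np <- np - 1L }
            else        { sos[s, 1:3] <- c(1,  1, 0); nn <- nn - 1L }
        } else if (np > 0 && nn > 0) {
            sos[s, 1:3] <- c(1, 0, -1); np <- np - 1L; nn <- nn - 1L
        } else if (np > 0) {
            sos[s, 1:3] <- c(1, -2, 1); np <- np - 2L
        } else {
            sos[s, 1:3] <- c(1, 2, 1); nn <- nn - 2L
        }
    }

    g <- Mod(sosResponse(sos, f_ref, fs))
    sos[1, 1:3] <- sos[1, 1:3] / g
    sos
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos matrix from [butterworthSos()].
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return complex vector of the response at `f`.
#' @export
sosResponse <- function(sos, f, fs) {
    z <- exp(-2i * pi * f / fs)
    h <- rep(1 + 0i, length(z))
    for (s in seq_len(nrow(sos))) {
        num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
        den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
        h <- h * num / den
    }
    h
}

# steady-state (step-input) initial conditions for one biquad, scaled by
# the caller with the first input sample
biquad_zi <- function(b, a) {
    den <- 1 + a[2] + a[3]
    yss <- if (abs(den) > .Machine$double.eps) sum(b) / den else 0
    z2 <- b[3] - a[3] * yss
    z1 <- b[2] - a[2] * yss + z2
    c(z1, z2)
}

sos_run <- function(sos, x) {
    for (s in seq_len(nrow(sos))) {
        b <- sos[s, 1:3]; a <- sos[s, 4:6]
        x <- biquad_filter(b, a, x, biquad_zi(b, a) * x[1])
    }
    x
}

#' Zero-phase filtering over second-order sections
#'
#' Filters forward and backward over the biquad cascade (squaring the
#' magnitude response, cancelling the phase). The signal is extended at both
#' ends by odd reflection and each section starts from its steady-state
#' response to the first sample, which suppresses start-up transients.
#'
#' @param sos matrix from [butterworthSos()].
#' @param x numeric signal.
#' @param padlen reflection padding length in samples; defaults to one
#'   second of signal (capped at `length(x) - 1`). Long impulse responses
#'   (very low cutoffs relative to `fs`) warrant at least a few times
#'   `fs / cutoff`.
#' @return filtered signal, same length as `x`.
#' @export
sosFiltFilt <- function(sos, x, padlen = NULL) {
    n <- length(x)
    if (n < 2L) stop("signal too short to filter")
    if (is.null(padlen)) padlen <- n - 1L
    p <- min(n - 1L, as.integer(padlen))
    if (p > 0L) {
        xe <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
    } else {
        xe <- x
    }
    y <- sos_run(sos, xe)
    y <- rev(sos_run(sos, rev(y)))
    if (p > 0L) y[(p + 1L):(p + n)] else y
}

# smallest 5-smooth (2^a 3^b 5^c) integer >= n; R's mixed-radix FFT is
# near-linear for such lengths but degrades badly on large prime factors
next_fast_len <- function(n) {
    if (n <= 6L) return(max(1L, as.integer(n)))
    best <- Inf
    p5 <- 1
    while (p5 < best) {
        p35 <- p5
        while (p35 < best) {
            p235 <- p35 * 2^max(0, ceiling(log2(n / p35)))
            if (p235 >= n) best <- min(best, p235)
            p35 <- p35 * 3
        }
        p5 <- p5 * 5
    }
    as.integer(best)
}

#' Hilbert envelope of a real signal
#'
#' Magnitude of the analytic signal, computed with the FFT method. The
#' transform is zero-padded to the next 5-smooth length (and truncated
#' after inversion) so the FFT stays fast for arbitrary signal lengths;
#' the padding perturbs only the last few cycles at the signal edge, which
#' the 5 Hz envelope smoothing and the centrally-evaluated tests tolerate.
#'
#' @param x numeric signal.
#' @return non-negative envelope, same length.
#' @export
hilbertEnvelope <- function(x) {
    n <- length(x)
    if (n == 0L) return(numeric(0))
    nfft <- next_fast_len(n)
    xp <- c(x, numeric(nfft - n))
    h <- numeric(nfft)
    if (nfft %% 2L == 0L) {
        h[1] <- 1; h[nfft / 2 + 1] <- 1
        if (nfft > 2L) h[2:(nfft / 2)] <- 2
    } else {
        h[1] <- 1
        if (nfft > 1L) h[2:((nfft + 1) / 2)] <- 2
    }
    Mod(stats::fft(stats::fft(xp) * h, inverse = TRUE) / nfft)[seq_len(n)]
}

# linear-interpolation resampling onto a uniform grid at out_rate Hz;
# adequate because every signal resampled here is already band-limited to
# 5 Hz, far below out_rate / 2
resample_uniform <- function(x, fs, out_rate) {
    n <- length(x)
    t_old <- (seq_len(n) - 1) / fs
    t_new <- seq(0, t_old[n], by = 1 / out_rate)
    stats::approx(t_old, x, xout = t_new)$y
}
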