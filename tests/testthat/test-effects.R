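# -- vibrato ---------------------------------------------------------------

test_that("jitter-free vibrato is exactly the stated sinusoid", {
    n <- SR
    t <- (0:(n - 1)) / SR
    cents <- ratio_to_cents(vibrato_track(vibrato_params(8.5, 40, 0), n, SR))
    expect_equal(cents, 40 * sin(2 * pi * 8.5 * t), tolerance = 1e-12)
    expect_equal(max(cents), 40, tolerance = 1e-4)
    expect_equal(min(cents), -40, tolerance = 1e-4)
    # zero mean over an integer number of cycles
    n_cyc <- floor(8.5) / 8.5 * SR
    expect_lt(abs(mean(cents[1:round(n_cyc)])), 1e-6)
    # depth halving halves the peak exactly
    half <- ratio_to_cents(vibrato_track(vibrato_params(8.5, 20, 0), n, SR))
    expect_equal(half, cents / 2, tolerance = 1e-12)
    # dominant component of the cents track sits at the rate
    spec <- Mod(fft(cents))[2:(n %/% 2)]
    expect_equal((which.max(spec)) / 1, 8.5 * n / SR, tolerance = 0.5)
})

test_that("depth 0 vibrato is the unity track", {
    expect_identical(vibrato_track(vibrato_params(8.5, 0, 0.3), 1000, SR),
                     rep(1, 1000))
})

test_that("rate jitter redraws per cycle within bounds, deterministically", {
    vp <- vibrato_params(8.5, 40, 0.30)
    a <- vibrato_track(vp, 2 * SR, SR, seed = 1)
    b <- vibrato_track(vp, 2 * SR, SR, seed = 2)
    a2 <- vibrato_track(vp, 2 * SR, SR, seed = 1)
    expect_identical(a, a2)
    expect_false(identical(a, b))
    for (track in list(a, b)) {
        cents <- ratio_to_cents(track)
        # instantaneous frequency per cycle from zero-crossing spacing of the
        # phase: recover cycle boundaries as upward zero crossings
        up <- which(cents[-1] > 0 & cents[-length(cents)] <= 0)
        freqs <- SR / diff(up)
        expect_true(all(freqs >= 8.5 * 0.7 - 0.1 & freqs <= 8.5 * 1.3 + 0.1))
    }
})

# -- onset detection -------------------------------------------------------

test_that("onset detector finds utterances causally and once each", {
    ip <- inflection_params("happy_rise")
    silence <- audio_signal(numeric(SR), SR)
    expect_identical(detect_onsets(silence, ip), list())

    two <- make_vowel(fixture_spec(f0 = 150, duration = 3,
                                   utterances = list(c(0.2, 1.2), c(2.2, 3))))
    ev <- detect_onsets(two, ip)
    expect_length(ev, 2L)
    expect_lt(abs(ev[[1]]$onset_time - 0.2), 0.025)
    expect_lt(abs(ev[[2]]$onset_time - 2.2), 0.025)

    tone <- make_tone(220, 1, amplitude = 1)
    ev1 <- detect_onsets(tone, ip)
    expect_length(ev1, 1L)
    expect_lt(ev1[[1]]$onset_time, 0.05)
})

# -- inflection profiles ---------------------------------------------------

test_that("happy inflection meets its endpoint/peak/zero contract", {
    ip <- inflection_params("happy_rise", 500, -200, 140)
    trk <- ratio_to_cents(inflection_track(list(inflection_event(0, ip)),
                                           SR, SR))
    expect_equal(trk[1], -200)
    expect_equal(max(trk), 140, tolerance = 1e-3)
    post <- trk[(round(0.5 * SR) + 1L):SR]
    expect_true(all(post == 0))
    # deviation occupies the full stated duration
    expect_gt(abs(trk[round(0.5 * SR) - 10L]), 1)
})

test_that("afraid inflection starts at its maximum and decays within bounds", {
    ip <- inflection_params("afraid_sinusoid", 500, -169.2, 169.2)
    trk <- ratio_to_cents(inflection_track(list(inflection_event(0, ip)),
                                           SR, SR))
    expect_equal(trk[1], 169.2)
    expect_true(all(abs(trk) <= 169.2 + 1e-9))
    expect_true(all(trk[(round(0.5 * SR) + 1L):SR] == 0))
})

test_that("inflection is zero outside events and later events replace earlier", {
    expect_identical(inflection_track(list(), 1000, SR), rep(1, 1000))
    ip <- inflection_params("happy_rise", 500, -200, 140)
    ev1 <- inflection_event(0.1, ip)
    ev2 <- inflection_event(0.3, ip)   # overlaps ev1's window
    trk <- ratio_to_cents(inflection_track(list(ev1, ev2), SR, SR))
    expect_true(all(trk[1:round(0.1 * SR)] == 0))
    # at 0.3 s the later event restarts the profile at its minimum
    expect_equal(trk[round(0.3 * SR) + 1L], -200)
    expect_true(all(trk[(round(0.8 * SR) + 2L):SR] == 0))
})

test_that("onset-gated inflection leaves inter-utterance silence untouched", {
    v <- make_vowel(fixture_spec(f0 = 150, duration = 3,
                                 utterances = list(c(0, 1), c(2, 3))))
    ip <- inflection_params("happy_rise", 500, -200, 140)
    ev <- detect_onsets(v, ip)
    trk <- inflection_track(ev, length(v$samples), SR)
    gap <- (round(1.6 * SR)):(round(1.9 * SR))   # well inside the silence
    expect_true(all(trk[gap] == 1))
})

# -- shelving filters ------------------------------------------------------

test_that("designed shelves meet the octave-slope contract exactly", {
    hp <- design_shelf(shelf_params("high_shelf", 8000, 9.5), SR)
    lp <- design_shelf(shelf_params("low_shelf", 8000, -12), SR)
    expect_equal(measure_filter_slope(hp), 9.5, tolerance = 1e-6)
    expect_equal(measure_filter_slope(lp), -12, tolerance = 1e-6)
    expect_lt(max(Mod(polyroot(rev(hp$a)))), 1)
    expect_lt(max(Mod(polyroot(rev(lp$a)))), 1)
})

test_that("shelf passband stays flat and stability holds across rates", {
    for (sr in c(16000, 44100, 48000)) {
        cutoff <- min(8000, sr / 5)      # keep the octave inside Nyquist
        for (sl in c(5.8, 6.6, 9.5, -7.8, -9.6, -12)) {
            kind <- if (sl > 0) "high_shelf" else "low_shelf"
            filt <- design_shelf(shelf_params(kind, cutoff, sl), sr)
            expect_lt(max(Mod(polyroot(rev(filt$a)))), 1)
            # far-from-cutoff passband within 0.5 dB of unity
            fpass <- if (kind == "high_shelf") c(0.01, 0.05) * cutoff
                     else c(0.01, 0.05) * cutoff
            h <- 20 * log10(Mod(emovox:::filter_response(filt, fpass, sr)))
            expect_true(all(abs(h) < 0.5))
        }
    }
})

test_that("zero slope designs the identity response", {
    filt <- design_shelf(shelf_params("high_shelf", 8000, 0), SR)
    h <- 20 * log10(Mod(emovox:::filter_response(filt, c(100, 1000, 8000, 16000), SR)))
    expect_true(all(abs(h) < 1e-9))
    expect_error(design_shelf(shelf_params("high_shelf", 23000, 9.5), SR),
                 "Nyquist")
})

test_that("impulse response spectrum matches the designed transfer function", {
    filt <- design_shelf(shelf_params("high_shelf", 8000, 9.5), SR)
    n <- 8192
    imp <- c(1, numeric(n - 1))
    ir <- apply_filter(filt, imp)$signal
    H_fft <- fft(ir)[2:(n %/% 2)]
    f <- (1:(n %/% 2 - 1)) * SR / n
    H_tf <- emovox:::filter_response(filt, f, SR)
    expect_lt(max(Mod(H_fft - H_tf) / Mod(H_tf)), 1e-6)
})

test_that("stateful IIR agrees with signal::filter and streams bit-exactly", {
    filt <- design_shelf(shelf_params("low_shelf", 8000, -12), SR)
    set.seed(5)
    x <- rnorm(10000)
    whole <- apply_filter(filt, x)$signal
    # independent route: the signal package's filter on identical coefficients
    ref <- as.numeric(signal::filter(filt$b, filt$a, x))
    expect_equal(whole, ref, tolerance = 1e-10)
    # block-wise with carried state is bit-identical to the whole call
    st <- filter_state(filt)
    got <- numeric(length(x))
    i <- 1L
    while (i <= length(x)) {
        j <- min(i + 127L, length(x))
        res <- apply_filter(filt, x[i:j], st)
        got[i:j] <- res$signal
        st <- res$state
        i <- j + 1L
    }
    expect_identical(got, whole)
    expect_error(apply_filter(filt, x, numeric(3)), "state dimension")
})
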