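# -- pitch oracle ----------------------------------------------------------

test_that("pitch oracle is accurate to a few cents on pure tones", {
    for (f in c(80, 150, 220, 440, 880, 1000)) {
        tr <- track_pitch(make_tone(f, 1), fmin = 70, fmax = 1100)
        expect_lt(abs(1200 * log2(median_f0(tr) / f)), 2,
                  label = paste("tone", f, "Hz"))
    }
})

test_that("pitch oracle handles vowels, silence and short input", {
    v <- vowel_fixture(f0 = 150, dur = 1)
    tr <- track_pitch(v)
    expect_lt(abs(median_f0(tr) - 150), 1)
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(tr$f0 >= 0, na.rm = TRUE))

    sil <- audio_signal(numeric(SR), SR)
    expect_true(all(is.na(track_pitch(sil)$f0)))

    expect_error(track_pitch(audio_signal(numeric(100), SR)), "too short")
})

# -- modulation measurement ------------------------------------------------

synthetic_track <- function(rate, depth, dur = 2, hop = 0.01, f0 = 220) {
    times <- seq(0, dur, by = hop)
    structure(list(times = times,
                   f0 = f0 * 2 ^ (depth * sin(2 * pi * rate * times) / 1200),
                   frame_hop = hop),
              class = "pitch_track")
}

test_that("modulation analysis recovers rate and depth from analytic tracks", {
    m <- measure_modulation(synthetic_track(8.5, 40))
    expect_lt(abs(m$rate - 8.5), 0.2)
    expect_lt(abs(m$depth - 40), 3)

    m20 <- measure_modulation(synthetic_track(6, 20))
    expect_lt(abs(m20$rate - 6), 0.2)
    expect_lt(abs(m20$depth - 20), 3)

    const <- synthetic_track(8.5, 0)
    expect_lt(measure_modulation(const)$depth, 0.5)

    short <- synthetic_track(8.5, 40, dur = 0.05)
    expect_error(measure_modulation(short), "cycles")
})

# -- filter-slope measurement ----------------------------------------------

test_that("filter-slope measurement reports the signed octave difference", {
    ident <- design_shelf(shelf_params("high_shelf", 8000, 0), SR)
    expect_equal(measure_filter_slope(ident), 0, tolerance = 1e-9)
    happy <- design_shelf(get_preset("happy", "high")$filter, SR)
    sad <- design_shelf(get_preset("sad", "high")$filter, SR)
    expect_equal(measure_filter_slope(happy), 9.5, tolerance = 0.5)
    expect_equal(measure_filter_slope(sad), -12, tolerance = 0.5)
    # an unstable coefficient set is rejected
    bad <- structure(list(b = c(1, 0), a = c(1, -1.5), kind = "high_shelf",
                          cutoff = 8000, sample_rate = SR),
                     class = "shelf_filter")
    expect_error(measure_filter_slope(bad), "unstable")
})

# -- recognition statistics ------------------------------------------------

example_table <- function() {
    m <- rbind(happy  = c(6, 2, 0, 0, 0),
               sad    = c(0, 8, 0, 0, 0),
               afraid = c(0, 2, 6, 0, 0),
               neutral = c(0, 0, 0, 8, 0))
    colnames(m) <- c("happy", "sad", "afraid", "neutral", "none")
    confusion_table(m)
}

test_that("unbiased hit rate and chance proportion match hand computations", {
    tab <- example_table()
    # row (6,2,0,0,0), column total 6 -> 36 / (8*6)
    expect_equal(unname(unbiased_hit_rate(tab, "happy")), 0.75)
    expect_equal(unname(chance_proportion(tab, "happy")), (8 * 6) / 32^2)
    expect_equal(unname(raw_hit_rate(tab, "happy")), 6 / 8)

    # perfectly diagonal table scores 1 everywhere
    perfect <- rbind(happy = c(8, 0, 0, 0, 0), sad = c(0, 8, 0, 0, 0),
                     afraid = c(0, 0, 8, 0, 0), neutral = c(0, 0, 0, 8, 0))
    colnames(perfect) <- c("happy", "sad", "afraid", "neutral", "none")
    expect_true(all(unbiased_hit_rate(confusion_table(perfect)) == 1))

    # a response label never used scores 0
    never <- rbind(happy = c(0, 8, 0, 0, 0), sad = c(0, 8, 0, 0, 0))
    colnames(never) <- c("happy", "sad", "afraid", "neutral", "none")
    expect_equal(unname(unbiased_hit_rate(confusion_table(never), "happy")), 0)
})

test_that("statistics agree with first-principles recomputation on random tables", {
    set.seed(42)
    cats <- c("happy", "sad", "afraid", "neutral")
    resp <- c(cats, "none")
    for (rep in 1:200) {
        m <- matrix(rpois(20, 3), 4, 5, dimnames = list(cats, resp))
        if (any(rowSums(m) == 0)) next
        tab <- confusion_table(m)
        for (cat in cats) {
            a <- m[cat, cat]; r <- sum(m[cat, ]); cl <- sum(m[, cat])
            # independent route: sensitivity times specificity
            hu_ref <- if (cl == 0) 0 else (a / r) * (a / cl)
            expect_equal(unname(unbiased_hit_rate(tab, cat)), hu_ref)
            expect_equal(unname(chance_proportion(tab, cat)),
                         (r / sum(m)) * (cl / sum(m)))
        }
    }
})

test_that("proportion index maps chance to 0.5 and is monotone", {
    expect_identical(proportion_index(0.20, 5), 0.5)
    expect_identical(proportion_index(1, 5), 1)
    expect_identical(proportion_index(0, 5), 0)
    p <- seq(0, 1, by = 0.01)
    expect_true(all(diff(proportion_index(p, 5)) > 0))
    for (k in c(2, 4, 5, 7)) {
        expect_equal(proportion_index(1 / k, k), 0.5)
    }
    expect_error(proportion_index(1.2, 5), "hit_rate")
    expect_error(proportion_index(0.5, 1), "k must")
})

test_that("proportion index depends only on the hit rate and k", {
    # shuffling the non-target response columns leaves pi unchanged
    set.seed(9)
    m <- matrix(rpois(20, 4), 4, 5,
                dimnames = list(c("happy", "sad", "afraid", "neutral"),
                                c("happy", "sad", "afraid", "neutral", "none")))
    tab <- confusion_table(m)
    pi1 <- proportion_index(raw_hit_rate(tab, "happy"), 5)
    shuffled <- m[, c("happy", "none", "sad", "neutral", "afraid")]
    # relabeled (permuted) non-target columns: same row, same diagonal cell
    pi2 <- proportion_index(raw_hit_rate(confusion_table(shuffled), "happy"), 5)
    expect_identical(pi1, pi2)
})

test_that("recognition score table assembles all four statistics", {
    sc <- recognition_scores(example_table(), k = 5)
    expect_identical(sc$category, c("happy", "sad", "afraid", "neutral"))
    expect_equal(sc$raw_hit_rate[1], 0.75)
    expect_equal(sc$proportion_index[1], proportion_index(0.75, 5))
    expect_equal(sc$unbiased_hit_rate[1], 0.75)
})

test_that("confusion tables round-trip through CSV", {
    tab <- example_table()
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    write_confusion_csv(tab, tmp)
    back <- read_confusion_csv(tmp)
    expect_equal(unclass(back), unclass(tab))
    expect_error(confusion_table(rbind(a = c(x = -1))), "non-negative")
})

test_that("arcsine paired comparison has the right shape and df", {
    x <- runif(20, 0.2, 0.6)
    r0 <- arcsine_compare(x, x)
    expect_identical(r0$statistic, 0)
    expect_identical(r0$df, 19)

    set.seed(3)
    hu <- runif(20, 0.25, 0.45); pc <- runif(20, 0.03, 0.08)
    r <- arcsine_compare(hu, pc)
    expect_identical(r$df, 19)          # n = 20 participants
    expect_gt(r$statistic, 0)
    expect_lt(r$p_value, 0.001)

    # family version applies Holm-Bonferroni across columns
    hu_m <- cbind(happy = runif(20, .3, .5), sad = runif(20, .3, .5),
                  afraid = runif(20, .3, .5))
    pc_m <- matrix(runif(60, .03, .08), 20, 3,
                   dimnames = list(NULL, colnames(hu_m)))
    fam <- arcsine_compare(hu_m, pc_m)
    expect_identical(nrow(fam), 3L)
    expect_identical(fam$p_holm, p.adjust(fam$p_value, "holm"))
    expect_true(all(fam$df == 19))

    expect_error(arcsine_compare(0.5, 0.4), "at least 2")
    expect_error(arcsine_compare(c(.1, .2), c(.1, .2, .3)), "equal length")
})
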