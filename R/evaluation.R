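# Independent verification oracles (pitch tracking, modulation analysis,
# filter response) and forced-choice emotion-recognition statistics.
#
# The pitch tracker is a YIN-style cumulative-mean-normalized difference
# tracker, deliberately independent of the delay-line synthesis path so it
# can serve as the oracle for the engine's pitch contracts.

#' Track the fundamental frequency of a signal
#'
#' YIN-style estimator: per frame, the lag-domain difference function is
#' computed over a fixed integration window (via FFT cross-correlation),
#' cumulative-mean-normalized, thresholded, and the selected minimum refined
#' by parabolic interpolation. Frames whose normalized minimum is weak or
#' whose level is below -60 dBFS are flagged unvoiced (`NA`).
#'
#' @param signal A mono [audio_signal()].
#' @param fmin,fmax Search range in Hz (default 70-1000).
#' @param hop Frame hop in seconds (default 0.01).
#' @param threshold Normalized-difference voicing threshold (default 0.1).
#' @return An object of class `"pitch_track"`: list with `times` (s, frame
#'   centers, strictly increasing), `f0` (Hz, `NA` where unvoiced) and
#'   `frame_hop` (s).
#' @export
track_pitch <- function(signal, fmin = 70, fmax = 1000, hop = 0.01,
                        threshold = 0.1) {
    stopifnot(inherits(signal, "audio_signal"))
    sr <- signal$sample_rate
    x <- signal$samples
    max_lag <- as.integer(ceiling(sr / fmin))
    min_lag <- max(2L, as.integer(floor(sr / fmax)))
    wi <- max_lag                       # integration window, samples
    frame_len <- wi + max_lag
    hop_n <- max(1L, as.integer(round(hop * sr)))
    if (length(x) < 2L * frame_len)
        stop("signal too short for pitch tracking at fmin = ", fmin, " Hz",
             call. = FALSE)

    starts <- seq(1L, length(x) - frame_len + 1L, by = hop_n)
    nfft <- 2 ^ ceiling(log2(2L * frame_len))
    f0 <- rep(NA_real_, length(starts))

    for (fi in seq_along(starts)) {
        fr <- x[starts[fi]:(starts[fi] + frame_len - 1L)]
        if (sqrt(mean(fr[seq_len(wi)] ^ 2)) < 1e-3) next  # < -60 dBFS

        # cross-correlation corr(tau) = sum_{j<wi} fr[j] * fr[j+tau], via FFT
        fa <- fft(c(fr, numeric(nfft - frame_len)))
        fb <- fft(c(fr[seq_len(wi)], numeric(nfft - wi)))
        cc <- Re(fft(fa * Conj(fb), inverse = TRUE)) / nfft
        corr <- cc[seq_len(max_lag + 1L)]          # lags 0..max_lag

        csq <- cumsum(fr ^ 2)
        e0 <- csq[wi]
        etau <- csq[(0:max_lag) + wi] - c(0, csq[seq_len(max_lag)])
        d <- e0 + etau - 2 * corr                  # difference function
        d[d < 0] <- 0                              # numerical guard

        # cumulative mean normalized difference
        dp <- rep(1, max_lag + 1L)
        cmean <- cumsum(d[-1L]) / seq_len(max_lag)
        dp[-1L] <- ifelse(cmean > 0, d[-1L] / cmean, 1)

        lo <- min_lag + 1L                         # index of lag min_lag
        cand <- which(dp[lo:(max_lag + 1L)] < threshold) + lo - 1L
        if (length(cand)) {
            tau <- cand[1L]
            while (tau < max_lag + 1L && dp[tau + 1L] < dp[tau]) tau <- tau + 1L
        } else {
            tau <- which.min(dp[lo:(max_lag + 1L)]) + lo - 1L
            if (dp[tau] > 0.5) next                # no clear periodicity
        }

        # parabolic interpolation on the raw difference function
        lag <- tau - 1L
        if (tau > 2L && tau <= max_lag) {
            a <- d[tau - 1L]; b <- d[tau]; cc3 <- d[tau + 1L]
            denom <- a - 2 * b + cc3
            if (denom > 0) lag <- lag + 0.5 * (a - cc3) / denom
        }
        f0[fi] <- sr / lag
    }
    structure(list(times = (starts - 1L + frame_len / 2) / sr, f0 = f0,
                   frame_hop = hop_n / sr),
              class = "pitch_track")
}

#' @export
print.pitch_track <- function(x, ...) {
    v <- sum(!is.na(x$f0))
    cat(sprintf("<pitch_track: %d frames (%d voiced), hop %.1f ms, median f0 %.2f Hz>\n",
                length(x$f0), v, 1000 * x$frame_hop,
                if (v) median(x$f0, na.rm = TRUE) else NA))
    invisible(x)
}

#' Median f0 of the voiced frames of a track
#' @param track A `"pitch_track"`.
#' @return Median f0 in Hz (`NA` if no voiced frame).
#' @export
median_f0 <- function(track) {
    stopifnot(inherits(track, "pitch_track"))
    if (!any(!is.na(track$f0))) return(NA_real_)
    median(track$f0, na.rm = TRUE)
}

#' Measure the dominant pitch modulation of a track
#'
#' Converts the longest contiguous voiced run of the track to cents around
#' its mean, finds the dominant spectral component above `min_rate` by FFT
#' (Hann window, zero-padded), refines the frequency by maximizing the
#' locally fitted sinusoid's explained energy, and reports the least-squares
#' amplitude at that frequency.
#'
#' @param track A `"pitch_track"` with at least two full modulation cycles
#'   of voiced frames.
#' @param min_rate Lowest modulation rate considered, Hz (default 2).
#' @return List with `rate` (Hz) and `depth` (cents).
#' @export
measure_modulation <- function(track, min_rate = 2) {
    stopifnot(inherits(track, "pitch_track"))
    voiced <- !is.na(track$f0)
    r <- rle(voiced)
    if (!any(r$values)) stop("no voiced frames in track", call. = FALSE)
    ends <- cumsum(r$lengths)
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    idx <- (ends[best] - r$lengths[best] + 1L):ends[best]
    f0 <- track$f0[idx]
    t <- track$times[idx]
    n <- length(f0)
    hop <- track$frame_hop
    if (n < ceiling(2 / (min_rate * hop)))
        stop("fewer than two modulation cycles of voiced frames", call. = FALSE)

    cents <- 1200 * log2(f0 / exp(mean(log(f0))))
    cents <- cents - mean(cents)

    win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
    nfft <- 2 ^ ceiling(log2(8L * n))
    spec <- Mod(fft(c(cents * win, numeric(nfft - n))))[seq_len(nfft %/% 2)]
    freqs <- (seq_len(nfft %/% 2) - 1L) / (nfft * hop)
    ok <- freqs >= min_rate & freqs <= 0.5 / hop
    if (!any(ok)) stop("modulation search band is empty", call. = FALSE)
    f_coarse <- freqs[ok][which.max(spec[ok])]

    # refine: least-squares sinusoid fit, maximizing explained energy
    fit_energy <- function(f) {
        X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
        cf <- qr.coef(qr(X), cents)
        sum((X %*% cf) ^ 2)
    }
    half_bin <- 1 / (n * hop)
    opt <- optimize(fit_energy, c(max(min_rate, f_coarse - half_bin),
                                  f_coarse + half_bin), maximum = TRUE)
    rate <- opt$maximum
    X <- cbind(cos(2 * pi * rate * t), sin(2 * pi * rate * t))
    cf <- qr.coef(qr(X), cents)
    list(rate = rate, depth = sqrt(sum(cf ^ 2)))
}

#' Measure the octave slope of a shelving filter
#'
#' Evaluates the designed transfer function's magnitude (dB) at the cutoff
#' and one octave toward the shelf, and returns the signed gain difference:
#' `|H|dB(2 fc) - |H|dB(fc)` for a high shelf, `|H|dB(fc) - |H|dB(fc/2)`
#' for a low shelf. This is the normative definition of the preset
#' "dB/octave" slope.
#'
#' @param filt A `"shelf_filter"` from [design_shelf()].
#' @param cutoff Cutoff in Hz (defaults to the filter's own).
#' @param kind Shelf kind (defaults to the filter's own).
#' @return Signed octave gain difference in dB.
#' @export
measure_filter_slope <- function(filt, cutoff = filt$cutoff, kind = filt$kind) {
    stopifnot(inherits(filt, "shelf_filter"))
    if (length(filt$a) > 1L) {
        roots <- polyroot(rev(filt$a))
        if (any(Mod(roots) >= 1))
            stop("unstable filter: pole on or outside the unit circle",
                 call. = FALSE)
    }
    octave_gain_diff(filt, cutoff, kind, filt$sample_rate)
}

# ---- forced-choice recognition statistics --------------------------------

#' Construct a confusion table of forced-choice counts
#'
#' Rows are intended (stimulus) categories, columns the chosen response
#' options; entries are non-negative trial counts. The response set may
#' include options (e.g. "none") that are never an intended category.
#'
#' @param counts Integer matrix (intended x chosen) with dimnames, or a
#'   data.frame whose first column is the intended label.
#' @return An object of class `"confusion_table"` (a validated matrix).
#' @export
confusion_table <- function(counts) {
    if (is.data.frame(counts)) {
        lab <- as.character(counts[[1L]])
        counts <- as.matrix(counts[-1L])
        rownames(counts) <- lab
    }
    if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must be a labeled intended x chosen matrix", call. = FALSE)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers", call. = FALSE)
    structure(counts, class = c("confusion_table", class(counts)))
}

#' Read/write a confusion table as plain CSV
#'
#' The CSV layout is one `intended` label column plus one column per
#' response option.
#'
#' @param path CSV file path.
#' @return For `read_confusion_csv`, a [confusion_table()].
#' @export
read_confusion_csv <- function(path) {
    confusion_table(read.csv(path, check.names = FALSE))
}

#' @rdname read_confusion_csv
#' @param table A [confusion_table()].
#' @export
write_confusion_csv <- function(table, path) {
    df <- data.frame(intended = rownames(table), unclass(table),
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Unbiased hit rate and individual chance proportion
#'
#' For an intended category with diagonal count `a`, row total `r` (trials
#' with that intended category) and column total `c` (uses of that response
#' label), the unbiased hit rate is `H_u = a^2 / (r * c)` — the product of
#' the category's sensitivity (`a/r`) and the response label's specificity
#' (`a/c`). Its chance-level counterpart is the individual chance
#' proportion `p_c = (r * c) / N^2` with `N` the grand total.
#'
#' @param table A [confusion_table()].
#' @param category Intended-category label (default: all intended
#'   categories).
#' @return Named numeric vector of `H_u` (or `p_c`) values in \[0, 1\].
#' @export
unbiased_hit_rate <- function(table, category = rownames(table)) {
    stopifnot(inherits(table, "confusion_table"))
    vapply(category, function(cat) {
        if (!cat %in% rownames(table))
            stop("unknown intended category: ", cat, call. = FALSE)
        r <- sum(table[cat, ])
        if (r == 0) stop("no trials for intended category ", cat, call. = FALSE)
        if (!cat %in% colnames(table)) return(0)
        cl <- sum(table[, cat])
        if (cl == 0) return(0)
        table[cat, cat] ^ 2 / (r * cl)
    }, numeric(1))
}

#' @rdname unbiased_hit_rate
#' @export
chance_proportion <- function(table, category = rownames(table)) {
    stopifnot(inherits(table, "confusion_table"))
    n <- sum(table)
    vapply(category, function(cat) {
        if (!cat %in% rownames(table))
            stop("unknown intended category: ", cat, call. = FALSE)
        r <- sum(table[cat, ])
        if (r == 0) stop("no trials for intended category ", cat, call. = FALSE)
        cl <- if (cat %in% colnames(table)) sum(table[, cat]) else 0
        (r * cl) / n ^ 2
    }, numeric(1))
}

#' Raw (biased) hit rate per intended category
#' @inheritParams unbiased_hit_rate
#' @return Named numeric vector of diagonal proportions.
#' @export
raw_hit_rate <- function(table, category = rownames(table)) {
    stopifnot(inherits(table, "confusion_table"))
    vapply(category, function(cat) {
        r <- sum(table[cat, ])
        if (r == 0) stop("no trials for intended category ", cat, call. = FALSE)
        if (!cat %in% colnames(table)) return(0)
        table[cat, cat] / r
    }, numeric(1))
}

#' Proportion index (chance-corrected accuracy)
#'
#' Transforms a raw hit rate `p` from a `k`-alternative forced-choice task
#' to a standard scale where chance (`p = 1/k`) maps to 0.5 and perfect
#' accuracy to 1.0: `pi = p*(k-1) / (1 + p*(k-2))`. It depends only on the
#' hit rate and the number of alternatives, so it is invariant to
#' relabeling of the non-target categories.
#'
#' @param hit_rate Raw hit rate(s) in \[0, 1\].
#' @param k Number of response alternatives (>= 2); 5 for a four-emotion
#'   task with an added "none of the above" option.
#' @return Proportion index value(s) in \[0, 1\].
#' @examples
#' proportion_index(0.2, k = 5)   # chance -> 0.5
#' @export
proportion_index <- function(hit_rate, k = 5L) {
    if (any(hit_rate < 0) || any(hit_rate > 1))
        stop("hit_rate must be in [0, 1]", call. = FALSE)
    if (k < 2) stop("k must be >= 2", call. = FALSE)
    hit_rate * (k - 1) / (1 + hit_rate * (k - 2))
}

#' Per-category recognition scores for one confusion table
#'
#' @param table A [confusion_table()].
#' @param k Number of response alternatives for the proportion index
#'   (default: number of response columns).
#' @return data.frame with columns `category`, `raw_hit_rate`,
#'   `proportion_index`, `unbiased_hit_rate`, `chance_proportion`.
#' @export
recognition_scores <- function(table, k = ncol(table)) {
    cats <- rownames(table)
    data.frame(category = cats,
               raw_hit_rate = unname(raw_hit_rate(table)),
               proportion_index = unname(proportion_index(raw_hit_rate(table), k)),
               unbiased_hit_rate = unname(unbiased_hit_rate(table)),
               chance_proportion = unname(chance_proportion(table)),
               row.names = NULL)
}

#' Paired comparison of arcsine-transformed proportions
#'
#' Applies the variance-stabilizing `asin(sqrt(x))` transform to paired
#' per-participant proportions (typically unbiased hit rates vs individual
#' chance proportions) and runs a paired t test; with matrix input (one
#' column per category), one test per column is run and the p values are
#' Holm-Bonferroni adjusted across that family.
#'
#' @param hu_values Numeric vector (or participants x categories matrix) of
#'   proportions in \[0, 1\].
#' @param pc_values Paired proportions, same shape.
#' @return For vectors: list with `statistic` (t), `df` (n - 1), `p_value`.
#'   For matrices: data.frame with one row per column plus Holm-adjusted
#'   `p_holm`.
#' @export
arcsine_compare <- function(hu_values, pc_values) {
    if (is.matrix(hu_values) || is.data.frame(hu_values)) {
        hu_values <- as.matrix(hu_values); pc_values <- as.matrix(pc_values)
        stopifnot(identical(dim(hu_values), dim(pc_values)))
        res <- lapply(seq_len(ncol(hu_values)), function(j)
            arcsine_compare(hu_values[, j], pc_values[, j]))
        out <- data.frame(
            category = colnames(hu_values) %||% as.character(seq_along(res)),
            t = vapply(res, `[[`, numeric(1), "statistic"),
            df = vapply(res, `[[`, numeric(1), "df"),
            p_value = vapply(res, `[[`, numeric(1), "p_value"))
        out$p_holm <- p.adjust(out$p_value, method = "holm")
        return(out)
    }
    if (length(hu_values) != length(pc_values))
        stop("paired samples must have equal length", call. = FALSE)
    if (length(hu_values) < 2L)
        stop("need at least 2 pairs", call. = FALSE)
    if (any(c(hu_values, pc_values) < 0) || any(c(hu_values, pc_values) > 1))
        stop("proportions must be in [0, 1]", call. = FALSE)
    d <- asin(sqrt(hu_values)) - asin(sqrt(pc_values))
    if (sd(d) == 0) {
        # degenerate paired sample (e.g. identical pairs): t is 0 by
        # convention when the mean difference is 0, +/-Inf otherwise
        tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        return(list(statistic = tt, df = length(d) - 1,
                    p_value = if (tt == 0) 1 else 0))
    }
    ht <- t.test(d)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}
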