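# Deterministic voice-like test signals with known ground truth, so every
# acoustic contract is testable without recordings.

#' Specification of a synthetic vowel fixture
#'
#' Describes a sustained-vowel signal: a band-limited glottal pulse train at
#' `f0` shaped by second-order formant resonators, gated to the given
#' utterance intervals (exact digital silence elsewhere).
#'
#' @param f0 Fundamental frequency in Hz (scalar), or a function of time
#'   (seconds) returning Hz for a pitch contour.
#' @param formants List of `c(center_hz, bandwidth_hz)` resonances; defaults
#'   to an /a/-like set (700/130, 1220/70, 2600/160).
#' @param utterances List of `c(start_s, end_s)` intervals (non-overlapping,
#'   inside `[0, duration]`); default one utterance spanning the whole
#'   duration.
#' @param amplitude Peak level in \[0, 1\] (default 0.8).
#' @param duration Total duration in seconds.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param seed RNG seed (reserved for optional noise components; the default
#'   fixture is fully deterministic).
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(f0 = 150, formants = list(c(700, 130), c(1220, 70),
                                                   c(2600, 160)),
                         utterances = NULL, amplitude = 0.8, duration = 1,
                         sample_rate = 44100, seed = 0L) {
    if (duration <= 0) stop("duration must be > 0", call. = FALSE)
    if (amplitude < 0 || amplitude > 1)
        stop("amplitude must be in [0, 1]", call. = FALSE)
    if (is.null(utterances)) utterances <- list(c(0, duration))
    ut <- do.call(rbind, utterances)   # NULL when empty: digital silence
    if (!is.null(ut) &&
        (any(ut[, 1] >= ut[, 2]) || any(ut < 0) || any(ut > duration + 1e-12)))
        stop("utterance intervals must be increasing and within [0, duration]",
             call. = FALSE)
    if (!is.null(ut) && nrow(ut) > 1L) {
        o <- order(ut[, 1])
        if (any(ut[o, 1][-1L] < ut[o, 2][-nrow(ut)]))
            stop("utterance intervals must not overlap", call. = FALSE)
    }
    f0min <- if (is.function(f0)) min(f0(seq(0, duration, length.out = 101)))
             else f0
    centers <- vapply(formants, `[`, numeric(1), 1L)
    if (f0min >= min(centers))
        stop("f0 must lie below the lowest formant center", call. = FALSE)
    structure(list(f0 = f0, formants = formants, utterances = utterances,
                   amplitude = amplitude, duration = duration,
                   sample_rate = sample_rate, seed = as.integer(seed)),
              class = "fixture_spec")
}

#' Generate an exact sinusoid
#'
#' @param frequency Tone frequency in Hz (must be below Nyquist).
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param amplitude Peak amplitude (default 1).
#' @return An [audio_signal()].
#' @examples
#' s <- make_tone(220, 0.5)
#' @export
make_tone <- function(frequency, duration, sample_rate = 44100, amplitude = 1) {
    if (frequency <= 0 || frequency >= sample_rate / 2)
        stop("frequency must be in (0, Nyquist)", call. = FALSE)
    n <- as.integer(round(duration * sample_rate))
    t <- (seq_len(n) - 1L) / sample_rate
    audio_signal(amplitude * sin(2 * pi * frequency * t), sample_rate)
}

# Peak-gain-normalized second-order resonator coefficients.
formant_resonator <- function(center, bandwidth, sample_rate) {
    r <- exp(-pi * bandwidth / sample_rate)
    th <- 2 * pi * center / sample_rate
    a <- c(1, -2 * r * cos(th), r ^ 2)
    h <- Mod(1 / sum(a * exp(-1i * th * (0:2))))
    list(b = 1 / h, a = a)
}

#' Synthesize a vowel-like fixture with known ground truth
#'
#' A band-limited glottal pulse train (harmonics up to 90% of Nyquist with
#' 1/k amplitude roll-off) is filtered through the formant resonators, gated
#' to the utterance intervals with 5-ms raised-cosine edges (exact silence
#' between utterances), and peak-normalized to the spec amplitude.
#'
#' @param spec A [fixture_spec()].
#' @return An [audio_signal()] with the ground truth (`f0`, `utterances`,
#'   `formants`) attached as `attr(, "ground_truth")`.
#' @examples
#' v <- make_vowel(fixture_spec(f0 = 150, duration = 0.5))
#' @export
make_vowel <- function(spec) {
    stopifnot(inherits(spec, "fixture_spec"))
    sr <- spec$sample_rate
    n <- as.integer(round(spec$duration * sr))
    t <- (seq_len(n) - 1L) / sr

    # instantaneous phase of the fundamental
    if (is.function(spec$f0)) {
        f0t <- spec$f0(t)
        phase <- 2 * pi * cumsum(f0t) / sr
        f0min <- min(f0t)
    } else {
        phase <- 2 * pi * spec$f0 * t
        f0min <- spec$f0
    }
    n_harm <- max(1L, floor(0.45 * sr / f0min))
    x <- numeric(n)
    for (k in seq_len(n_harm)) x <- x + cos(k * phase) / k

    for (fm in spec$formants) {
        res <- formant_resonator(fm[1L], fm[2L], sr)
        x <- .iir_df2t_cpp(res$b, res$a, x, numeric(2))
    }

    # utterance gate with raised-cosine edges; exact zero outside
    gate <- numeric(n)
    edge <- max(1L, as.integer(round(0.005 * sr)))
    for (u in spec$utterances) {
        i0 <- as.integer(floor(u[1L] * sr)) + 1L
        i1 <- min(n, as.integer(ceiling(u[2L] * sr)))
        len <- i1 - i0 + 1L
        g <- rep(1, len)
        e <- min(edge, len %/% 2L)
        if (e > 0L) {
            ramp <- 0.5 - 0.5 * cos(pi * (seq_len(e) - 0.5) / e)
            g[seq_len(e)] <- ramp
            g[(len - e + 1L):len] <- rev(ramp)
        }
        gate[i0:i1] <- g
    }
    x <- x * gate
    peak <- max(abs(x))
    if (peak > 0) x <- x * (spec$amplitude / peak)

    out <- audio_signal(x, sr)
    attr(out, "ground_truth") <- list(f0 = spec$f0,
                                      utterances = spec$utterances,
                                      formants = spec$formants)
    out
}
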