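# Block-based causal processing framework and the shared delay-line
# (harmonizer) pitch-shifting engine on which constant shift, vibrato, and
# inflection all ride.

#' Convert a pitch interval in cents to a frequency ratio
#'
#' 100 cents = one equal-tempered semitone; the ratio is `2^(cents/1200)`.
#'
#' @param cents Pitch interval(s) in cents (finite numeric).
#' @return Dimensionless multiplicative frequency ratio(s).
#' @examples
#' cents_to_ratio(1200)  # one octave -> 2
#' ratio_to_cents(cents_to_ratio(50))
#' @export
cents_to_ratio <- function(cents) {
    if (!is.numeric(cents) || any(!is.finite(cents)))
        stop("`cents` must be finite numeric", call. = FALSE)
    2 ^ (cents / 1200)
}

#' @rdname cents_to_ratio
#' @param ratio Frequency ratio(s), strictly positive.
#' @export
ratio_to_cents <- function(ratio) {
    if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
        stop("`ratio` must be finite positive numeric", call. = FALSE)
    1200 * log2(ratio)
}

#' Engine configuration
#'
#' `max_delay` (the harmonizer's *window*) fixes the delay-line memory and
#' therefore the algorithmic latency: `round(max_delay * sample_rate)`
#' samples. The default window is 10 ms; the default block size follows the
#' 128-sample signal-vector recommendation for real-time use.
#'
#' @param block_size Processing block length in samples (default 128).
#' @param max_delay Harmonizer window in seconds (default 0.010).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return An object of class `"engine_config"`.
#' @export
engine_config <- function(block_size = 128L, max_delay = 0.010,
                          sample_rate = 44100) {
    block_size <- as.integer(block_size)
    if (block_size < 1L) stop("block_size must be >= 1", call. = FALSE)
    if (max_delay * sample_rate < 2)
        stop("max_delay * sample_rate must be >= 2 samples", call. = FALSE)
    structure(list(block_size = block_size, max_delay = max_delay,
                   sample_rate = sample_rate),
              class = "engine_config")
}

#' Algorithmic latency of an engine configuration, in samples
#' @param config An [engine_config()].
#' @return Latency in samples (`round(max_delay * sample_rate)`).
#' @export
engine_latency <- function(config) {
    as.integer(round(config$max_delay * config$sample_rate))
}

# Tap wrap modulus: the largest even integer <= the latency in samples. An
# even modulus lets the primary tap start at the exactly integer delay
# wrap_len/2 where its crossfade gain is exactly 1, making the unity-ratio
# transform a bit-exact pure delay.
engine_wrap_len <- function(config) {
    2 * (engine_latency(config) %/% 2L)
}

#' Create a pitch-modulator (harmonizer) state
#'
#' The harmonizer realizes pitch shifting as a time-varying delay: the tap
#' delay drifts at `(1 - ratio)` samples per sample and wraps within the
#' window, while a second tap half a wrap period behind is crossfaded in with
#' complementary raised-cosine gains (gain sum exactly 1 at every sample).
#' State advances block-wise so that concatenated block outputs are
#' bit-identical to one whole-signal call.
#'
#' @param config An [engine_config()].
#' @return An object of class `"pitch_modulator"` (mutable environment).
#' @seealso [process_block()]
#' @export
pitch_modulator <- function(config = engine_config()) {
    stopifnot(inherits(config, "engine_config"))
    wrap_len <- engine_wrap_len(config)
    st <- new.env(parent = emptyenv())
    st$config <- config
    st$wrap_len <- wrap_len
    st$buf <- numeric(wrap_len + 2L)   # ring buffer of past input
    st$pos <- 0L                       # C-side write index
    st$d1 <- wrap_len / 2              # primary tap delay, samples
    class(st) <- "pitch_modulator"
    st
}

#' Process one block through the harmonizer
#'
#' @param state A [pitch_modulator()] (advanced in place).
#' @param block An [audio_signal()] or numeric vector.
#' @param ratio_track Per-sample pitch ratio sequence, same length as the
#'   block; all values must lie in \[0.5, 2\] (the subtle-transformation
#'   operating range; larger transpositions make the tap drift pathological).
#' @return The processed block as an [audio_signal()], same length as input.
#' @export
process_block <- function(state, block, ratio_track) {
    stopifnot(inherits(state, "pitch_modulator"))
    sr <- state$config$sample_rate
    sig <- as_audio_signal(block, sr)
    x <- sig$samples
    if (length(ratio_track) == 1L) ratio_track <- rep(ratio_track, length(x))
    if (length(ratio_track) != length(x))
        stop("ratio_track length (", length(ratio_track),
             ") must equal block length (", length(x), ")", call. = FALSE)
    if (length(x) && (min(ratio_track) < 0.5 || max(ratio_track) > 2))
        stop("pitch ratios outside [0.5, 2] are not supported", call. = FALSE)
    pos_io <- state$pos
    d1_io <- state$d1
    y <- .harmonizer_process_cpp(x, as.numeric(ratio_track), state$buf,
                                 pos_io, d1_io, state$wrap_len)
    state$pos <- pos_io
    state$d1 <- d1_io
    audio_signal(y, sig$sample_rate)
}

#' Process a whole signal through the harmonizer, block by block
#'
#' Convenience wrapper that chunks the signal into `config$block_size`
#' blocks. By the streaming-equivalence contract the result does not depend
#' on the block size.
#'
#' @param signal An [audio_signal()].
#' @param ratio_track Per-sample ratio sequence (length 1 broadcasts).
#' @param config An [engine_config()]; its sample rate is taken from the
#'   signal.
#' @param block_size Optional override of `config$block_size`.
#' @return The pitch-shifted [audio_signal()], same length as input.
#' @export
pitch_shift_signal <- function(signal, ratio_track,
                               config = engine_config(sample_rate = signal$sample_rate),
                               block_size = config$block_size) {
    stopifnot(inherits(signal, "audio_signal"))
    n <- length(signal$samples)
    if (length(ratio_track) == 1L) ratio_track <- rep(ratio_track, n)
    if (length(ratio_track) != n)
        stop("ratio_track length must equal signal length", call. = FALSE)
    if (config$sample_rate != signal$sample_rate)
        config$sample_rate <- signal$sample_rate
    pm <- pitch_modulator(config)
    out <- numeric(n)
    i <- 1L
    while (i <= n) {
        j <- min(i + block_size - 1L, n)
        out[i:j] <- process_block(pm, signal$samples[i:j], ratio_track[i:j])$samples
        i <- j + 1L
    }
    audio_signal(out, signal$sample_rate)
}

#' Accumulate pitch-modulation factors
#'
#' The constant shift, vibrato and inflection stages each emit a
#' multiplicative pitch factor; the engine applies their element-wise
#' product (equivalently, the sum of their cents profiles), so the factors
#' commute and a unity factor is neutral.
#'
#' @param constant Scalar or per-sample ratio (constant shift stage).
#' @param vibrato Scalar or per-sample ratio (vibrato stage).
#' @param inflection Scalar or per-sample ratio (inflection stage).
#' @return Per-sample ratio sequence.
#' @export
accumulate_ratios <- function(constant = 1, vibrato = 1, inflection = 1) {
    lens <- c(length(constant), length(vibrato), length(inflection))
    n <- max(lens)
    if (any(lens != 1L & lens != n))
        stop("ratio tracks must share a common length (scalars broadcast)",
             call. = FALSE)
    as.numeric(constant) * as.numeric(vibrato) * as.numeric(inflection)
}
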