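#' Mono audio signal
#'
#' The unit every effect consumes and produces: a mono sample sequence
#' (dimensionless amplitudes, nominally in \[-1, 1\]) plus its sample rate.
#' All transformation operations preserve the sample count exactly (no time
#' stretching: the engine is causal and real-time capable by construction).
#'
#' @param samples Numeric vector of sample amplitudes.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @return An object of class `"audio_signal"` with fields `samples` and
#'   `sample_rate`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 220 * (0:999) / 44100), 44100)
#' duration(s)
#' @export
audio_signal <- function(samples, sample_rate) {
    if (!is.numeric(samples))
        stop("`samples` must be numeric", call. = FALSE)
    if (is.matrix(samples) && ncol(samples) > 1L)
        stop("stereo input is not supported: supply a mono signal", call. = FALSE)
    if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
        !is.finite(sample_rate) || sample_rate <= 0)
        stop("`sample_rate` must be a positive finite scalar", call. = FALSE)
    structure(list(samples = as.numeric(samples),
                   sample_rate = as.numeric(sample_rate)),
              class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
    cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), peak %.4f>\n",
                length(x$samples), x$sample_rate, duration(x),
                if (length(x$samples)) max(abs(x$samples)) else 0))
    invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param x An [audio_signal()].
#' @return Duration in seconds.
#' @export
duration <- function(x) {
    stopifnot(inherits(x, "audio_signal"))
    length(x$samples) / x$sample_rate
}

as_audio_signal <- function(x, sample_rate) {
    if (inherits(x, "audio_signal")) x else audio_signal(x, sample_rate)
}

#' Peak-normalize a signal to a target level
#'
#' Rescales the signal by a pure gain so that its maximum absolute sample
#' equals the target level in dBFS (0 dBFS = full scale 1.0). Digital silence
#' is returned unchanged with a warning. Normalization is idempotent.
#'
#' @param signal An [audio_signal()].
#' @param target_dbfs Target peak level in dBFS (default -1).
#' @return The rescaled [audio_signal()].
#' @examples
#' s <- audio_signal(0.5 * sin(2 * pi * 100 * (0:999) / 8000), 8000)
#' max(abs(peak_normalize(s, 0)$samples))
#' @export
peak_normalize <- function(signal, target_dbfs = -1) {
    stopifnot(inherits(signal, "audio_signal"))
    peak <- if (length(signal$samples)) max(abs(signal$samples)) else 0
    if (peak == 0) {
        warning("signal is digital silence; normalization is a no-op")
        return(signal)
    }
    gain <- 10 ^ (target_dbfs / 20) / peak
    audio_signal(signal$samples * gain, signal$sample_rate)
}
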