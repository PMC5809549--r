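# Minimal RIFF/WAVE codec: PCM 16- and 24-bit plus IEEE float32, mono.
# Written with readBin/writeBin; all times/levels elsewhere in the package are
# specified in seconds/Hz/dBFS so nothing depends on a particular rate.

#' Read a mono WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float32 encodings. Integer PCM is
#' scaled to \[-1, 1) by the conventional 2^(bits-1) divisor. Stereo and other
#' multi-channel files are rejected: the transformation pipeline is defined
#' for a single voice channel.
#'
#' @param path Path to a WAV file.
#' @return An [audio_signal()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    con <- file(path, "rb")
    on.exit(close(con))

    riff <- readChar(con, 4, useBytes = TRUE)
    if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
    readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
    wave <- readChar(con, 4, useBytes = TRUE)
    if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

    fmt <- NULL
    repeat {
        id <- readChar(con, 4, useBytes = TRUE)
        if (length(id) == 0L || nchar(id) < 4L)
            stop("no data chunk found in ", path, call. = FALSE)
        sz <- readBin(con, "integer", 1, 4, endian = "little")
        if (identical(id, "fmt ")) {
            raw <- readBin(con, "raw", sz)
            fmt <- list(
                format   = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
                channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
                rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
                bits     = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little"))
            if (fmt$format == 65534L && sz >= 24L)  # WAVE_FORMAT_EXTENSIBLE
                fmt$format <- readBin(raw[25:26], "integer", 1, 2, signed = FALSE, endian = "little")
        } else if (identical(id, "data")) {
            if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
            if (fmt$channels != 1L)
                stop("stereo/multichannel input is not supported (",
                     fmt$channels, " channels); supply a mono file", call. = FALSE)
            bytes <- readBin(con, "raw", sz)
            samples <- decode_wav_data(bytes, fmt)
            return(audio_signal(samples, fmt$rate))
        } else {
            readBin(con, "raw", sz + (sz %% 2L))  # skip (chunks are word-aligned)
            next
        }
        if (sz %% 2L == 1L) readBin(con, "raw", 1)
    }
}

decode_wav_data <- function(bytes, fmt) {
    if (fmt$format == 1L && fmt$bits == 16L) {
        readBin(bytes, "integer", length(bytes) / 2, 2,
                signed = TRUE, endian = "little") / 32768
    } else if (fmt$format == 1L && fmt$bits == 24L) {
        n <- length(bytes) / 3
        m <- matrix(as.integer(bytes), nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
    } else if (fmt$format == 3L && fmt$bits == 32L) {
        readBin(bytes, "double", length(bytes) / 4, 4, endian = "little")
    } else {
        stop("unsupported WAV encoding: format tag ", fmt$format, ", ",
             fmt$bits, " bits", call. = FALSE)
    }
}

#' Write a mono WAV file
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bit_depth One of 16, 24 (integer PCM) or 32 (IEEE float). Integer
#'   output is clipped to \[-1, 1 - 2^-(bits-1)\] and quantized only at write
#'   time; all internal processing is double precision.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = 16) {
    stopifnot(inherits(signal, "audio_signal"))
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(16L, 24L, 32L))
        stop("bit_depth must be 16, 24 or 32", call. = FALSE)
    x <- signal$samples
    rate <- as.integer(round(signal$sample_rate))
    fmt_tag <- if (bit_depth == 32L) 3L else 1L
    block <- bit_depth %/% 8L
    data_size <- length(x) * block

    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("RIFF", con, eos = NULL)
    writeBin(as.integer(36L + data_size), con, 4, endian = "little")
    writeChar("WAVE", con, eos = NULL)
    writeChar("fmt ", con, eos = NULL)
    writeBin(16L, con, 4, endian = "little")
    writeBin(fmt_tag, con, 2, endian = "little")
    writeBin(1L, con, 2, endian = "little")                 # mono
    writeBin(rate, con, 4, endian = "little")
    writeBin(as.integer(rate * block), con, 4, endian = "little")
    writeBin(as.integer(block), con, 2, endian = "little")
    writeBin(bit_depth, con, 2, endian = "little")
    writeChar("data", con, eos = NULL)
    writeBin(as.integer(data_size), con, 4, endian = "little")

    if (bit_depth == 32L) {
        writeBin(x, con, 4, endian = "little")
    } else {
        full <- 2 ^ (bit_depth - 1)
        q <- as.integer(pmax(pmin(round(x * full), full - 1), -full))
        if (bit_depth == 16L) {
            writeBin(q, con, 2, endian = "little")
        } else {
            u <- ifelse(q < 0L, q + 16777216L, q)
            b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
            writeBin(as.raw(b), con)
        }
    }
    invisible(path)
}
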