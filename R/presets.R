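# Registry of the validated emotional transformations: happy/sad/afraid at
# three intensity levels ("high" is the nominal level), with gender-specific
# parameters for afraid only.

.preset_table <- list(
    happy = list(
        pitch = c(low = 29.5, medium = 40.9, high = 50.0),
        inflection = list(
            shape = "happy_rise", duration_ms = 500,
            min = c(low = -144.8, medium = -158.9, high = -200),
            max = c(low = 101.3, medium = 111.3, high = 140)),
        filter = list(kind = "high_shelf", cutoff = 8000,
                      slope = c(low = 5.8, medium = 6.6, high = 9.5))
    ),
    sad = list(
        pitch = c(low = -39.8, medium = -56.2, high = -70.0),
        filter = list(kind = "low_shelf", cutoff = 8000,
                      slope = c(low = -7.8, medium = -9.6, high = -12))
    ),
    afraid = list(
        vibrato = list(
            rate = 8.5, rate_jitter = 0.30,
            depth = list(male = c(low = 26.1, medium = 33.8, high = 40.0),
                         female = c(low = 13.7, medium = 20.2, high = 33.0))),
        inflection = list(
            shape = "afraid_sinusoid", duration_ms = 500,
            bound = list(male = c(low = 109.3, medium = 141.0, high = 169.2),
                         female = c(low = 50.2, medium = 101.1, high = 158.6)))
    ),
    neutral = list()
)

#' Look up a validated emotional transformation preset
#'
#' Returns the full recipe (`transform_spec`) for one emotion at one
#' intensity level: which of the four atomic effects are active and with
#' what parameters. `"high"` is the nominal (strongest validated) level.
#' Happy activates pitch-shift up, inflection and a high shelf; sad
#' activates pitch-shift down and a low shelf; afraid activates vibrato and
#' inflection, with gender-specific depths and bounds; neutral activates
#' nothing. Only the afraid parameters depend on the speaker's gender.
#'
#' @param emotion `"happy"`, `"sad"`, `"afraid"` or `"neutral"`.
#' @param level `"low"`, `"medium"` or `"high"` (nominal).
#' @param gender `"male"`, `"female"`, or `"unspecified"`. Required for
#'   afraid; `"unspecified"` falls back to the male parameter set with a
#'   warning.
#' @return An object of class `"transform_spec"` with components
#'   `pitch_shift_cents`, `vibrato`, `inflection`, `filter` (absent effects
#'   are `NULL`).
#' @examples
#' get_preset("happy", "high")
#' @export
get_preset <- function(emotion = c("happy", "sad", "afraid", "neutral"),
                       level = c("high", "medium", "low"),
                       gender = NULL) {
    emotion <- match.arg(emotion)
    level <- match.arg(level)
    p <- .preset_table[[emotion]]

    g <- NULL
    if (emotion == "afraid") {
        if (is.null(gender))
            stop("the afraid transformation requires `gender` (\"male\" or ",
                 "\"female\")", call. = FALSE)
        gender <- match.arg(gender, c("male", "female", "unspecified"))
        g <- gender
        if (gender == "unspecified") {
            warning("gender \"unspecified\": using the male afraid parameters")
            g <- "male"
        }
    } else if (!is.null(gender)) {
        gender <- match.arg(gender, c("male", "female", "unspecified"))
    }

    spec <- list(emotion = emotion, level = level,
                 gender = if (is.null(gender)) "unspecified" else gender,
                 pitch_shift_cents = NULL, vibrato = NULL,
                 inflection = NULL, filter = NULL)

    if (!is.null(p$pitch))
        spec$pitch_shift_cents <- unname(p$pitch[[level]])
    if (!is.null(p$vibrato))
        spec$vibrato <- vibrato_params(rate = p$vibrato$rate,
                                       depth = unname(p$vibrato$depth[[g]][[level]]),
                                       rate_jitter = p$vibrato$rate_jitter)
    if (!is.null(p$inflection)) {
        inf <- p$inflection
        if (inf$shape == "happy_rise") {
            mn <- unname(inf$min[[level]]); mx <- unname(inf$max[[level]])
        } else {
            b <- unname(inf$bound[[g]][[level]]); mn <- -b; mx <- b
        }
        spec$inflection <- inflection_params(profile_shape = inf$shape,
                                             duration_ms = inf$duration_ms,
                                             min_cents = mn, max_cents = mx)
    }
    if (!is.null(p$filter))
        spec$filter <- shelf_params(kind = p$filter$kind,
                                    cutoff = p$filter$cutoff,
                                    slope = unname(p$filter$slope[[level]]))
    structure(spec, class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
    cat(sprintf("<transform_spec: %s / %s / %s>\n", x$emotion, x$level, x$gender))
    if (!is.null(x$pitch_shift_cents))
        cat(sprintf("  pitch shift: %+g cents\n", x$pitch_shift_cents))
    if (!is.null(x$vibrato))
        cat(sprintf("  vibrato: %g Hz, %g cents depth, %g%% rate jitter\n",
                    x$vibrato$rate, x$vibrato$depth, 100 * x$vibrato$rate_jitter))
    if (!is.null(x$inflection))
        cat(sprintf("  inflection: %s, %g ms, [%g, %g] cents\n",
                    x$inflection$profile_shape, x$inflection$duration_ms,
                    x$inflection$min_cents, x$inflection$max_cents))
    if (!is.null(x$filter))
        cat(sprintf("  filter: %s, %g Hz cutoff, %+g dB/octave\n",
                    x$filter$kind, x$filter$cutoff, x$filter$slope))
    if (is.null(x$pitch_shift_cents) && is.null(x$vibrato) &&
        is.null(x$inflection) && is.null(x$filter))
        cat("  (no active effects: unity transform)\n")
    invisible(x)
}

#' Tabulate every validated preset
#'
#' One row per emotion x level x gender with all numeric parameters, for
#' audit and for the CLI's `--list-presets`.
#'
#' @return A data.frame.
#' @export
list_presets <- function() {
    rows <- list()
    for (emotion in c("happy", "sad", "afraid", "neutral")) {
        genders <- if (emotion == "afraid") c("male", "female") else "unspecified"
        for (gender in genders) for (level in c("low", "medium", "high")) {
            s <- get_preset(emotion, level,
                            gender = if (emotion == "afraid") gender else NULL)
            rows[[length(rows) + 1L]] <- data.frame(
                emotion = emotion, level = level, gender = gender,
                pitch_shift_cents = s$pitch_shift_cents %||% NA_real_,
                vibrato_rate_hz = s$vibrato$rate %||% NA_real_,
                vibrato_depth_cents = s$vibrato$depth %||% NA_real_,
                vibrato_rate_jitter = s$vibrato$rate_jitter %||% NA_real_,
                inflection_duration_ms = s$inflection$duration_ms %||% NA_real_,
                inflection_min_cents = s$inflection$min_cents %||% NA_real_,
                inflection_max_cents = s$inflection$max_cents %||% NA_real_,
                filter_kind = s$filter$kind %||% NA_character_,
                filter_cutoff_hz = s$filter$cutoff %||% NA_real_,
                filter_slope_db_oct = s$filter$slope %||% NA_real_)
        }
    }
    do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a transform spec to a plain-text config list
#'
#' Units are embedded in the key names (`*_cents`, `*_hz`, `*_ms`,
#' `*_db_oct`) so configs are self-describing; [read_transform_config()] /
#' [write_transform_config()] round-trip the registry bit-exactly through
#' YAML.
#'
#' @param spec A `"transform_spec"`.
#' @return A plain nested list suitable for `yaml::write_yaml()`.
#' @export
spec_to_config <- function(spec) {
    stopifnot(inherits(spec, "transform_spec"))
    cfg <- list(emotion = spec$emotion, level = spec$level,
                gender = spec$gender)
    if (!is.null(spec$pitch_shift_cents))
        cfg$pitch_shift_cents <- spec$pitch_shift_cents
    if (!is.null(spec$vibrato))
        cfg$vibrato <- list(rate_hz = spec$vibrato$rate,
                            depth_cents = spec$vibrato$depth,
                            rate_jitter = spec$vibrato$rate_jitter)
    if (!is.null(spec$inflection))
        cfg$inflection <- list(profile_shape = spec$inflection$profile_shape,
                               duration_ms = spec$inflection$duration_ms,
                               min_cents = spec$inflection$min_cents,
                               max_cents = spec$inflection$max_cents,
                               rms_window_ms = spec$inflection$rms_window_ms,
                               rms_threshold_dbfs = spec$inflection$rms_threshold_dbfs,
                               rearm_dbfs = spec$inflection$rearm_dbfs,
                               rearm_gap_ms = spec$inflection$rearm_gap_ms)
    if (!is.null(spec$filter))
        cfg$filter <- list(kind = spec$filter$kind,
                           cutoff_hz = spec$filter$cutoff,
                           slope_db_oct = spec$filter$slope,
                           order = spec$filter$order)
    cfg
}

#' @rdname spec_to_config
#' @param cfg A config list as produced by [spec_to_config()].
#' @return A `"transform_spec"`.
#' @export
config_to_spec <- function(cfg) {
    spec <- list(emotion = cfg$emotion %||% "neutral",
                 level = cfg$level %||% "high",
                 gender = cfg$gender %||% "unspecified",
                 pitch_shift_cents = cfg$pitch_shift_cents,
                 vibrato = NULL, inflection = NULL, filter = NULL)
    if (!is.null(cfg$vibrato))
        spec$vibrato <- vibrato_params(rate = cfg$vibrato$rate_hz,
                                       depth = cfg$vibrato$depth_cents,
                                       rate_jitter = cfg$vibrato$rate_jitter)
    if (!is.null(cfg$inflection)) {
        ip <- cfg$inflection
        defaults <- inflection_params(profile_shape = ip$profile_shape,
                                      duration_ms = ip$duration_ms,
                                      min_cents = ip$min_cents,
                                      max_cents = ip$max_cents)
        for (k in c("rms_window_ms", "rms_threshold_dbfs", "rearm_dbfs",
                    "rearm_gap_ms"))
            if (!is.null(ip[[k]])) defaults[[k]] <- ip[[k]]
        spec$inflection <- defaults
    }
    if (!is.null(cfg$filter))
        spec$filter <- shelf_params(kind = cfg$filter$kind,
                                    cutoff = cfg$filter$cutoff_hz,
                                    slope = cfg$filter$slope_db_oct,
                                    order = cfg$filter$order %||% 5L)
    structure(spec, class = "transform_spec")
}

#' @rdname spec_to_config
#' @param path File path of a YAML config.
#' @export
write_transform_config <- function(spec, path) {
    yaml::write_yaml(spec_to_config(spec), path, precision = 15L)
    invisible(path)
}

#' @rdname spec_to_config
#' @export
read_transform_config <- function(path) {
    config_to_spec(yaml::read_yaml(path))
}

#' Apply an emotional transformation to a signal
#'
#' Composes the active effects of a [get_preset()] spec: the constant shift,
#' vibrato and inflection cents profiles are accumulated into one per-sample
#' ratio track (their product), driven through the shared harmonizer engine,
#' and the shelving filter (if any) is applied last so the spectral shaping
#' is not itself pitch-shifted. Length-preserving, causal, and deterministic
#' given `seed`; a neutral spec is the unity transform (bit-identical to the
#' input after compensating the engine's constant delay).
#'
#' @param spec A `"transform_spec"`.
#' @param signal A mono [audio_signal()].
#' @param seed RNG seed for the vibrato rate jitter.
#' @param config An [engine_config()] (sample rate is taken from `signal`).
#' @param block_size Processing block length in samples; the output is
#'   bit-independent of it (streaming equivalence).
#' @param stages Subset of `c("pitch", "vibrato", "inflection", "filter")`
#'   to enable, for staged measurement; defaults to all.
#' @return The transformed [audio_signal()], with the resolved parameters in
#'   `attr(, "log")` and detected onsets in `attr(, "events")`.
#' @export
apply_transform <- function(spec, signal, seed = 0L,
                            config = engine_config(sample_rate = signal$sample_rate),
                            block_size = config$block_size,
                            stages = c("pitch", "vibrato", "inflection", "filter")) {
    stopifnot(inherits(spec, "transform_spec"), inherits(signal, "audio_signal"))
    stages <- match.arg(stages, several.ok = TRUE)
    n <- length(signal$samples)
    sr <- signal$sample_rate
    config$sample_rate <- sr

    const_ratio <- if (!is.null(spec$pitch_shift_cents) && "pitch" %in% stages)
        cents_to_ratio(spec$pitch_shift_cents) else 1
    vib <- if (!is.null(spec$vibrato) && "vibrato" %in% stages)
        vibrato_track(spec$vibrato, n, sr, seed = seed) else 1

    events <- list()
    infl <- 1
    if (!is.null(spec$inflection) && "inflection" %in% stages) {
        events <- detect_onsets(signal, spec$inflection)
        infl <- inflection_track(events, n, sr)
    }
    track <- accumulate_ratios(const_ratio, vib, infl)
    if (length(track) == 1L) track <- rep(track, n)

    out <- pitch_shift_signal(signal, track, config, block_size = block_size)

    if (!is.null(spec$filter) && "filter" %in% stages) {
        filt <- design_shelf(spec$filter, sr)
        st <- filter_state(filt)
        y <- numeric(n)
        i <- 1L
        while (i <= n) {
            j <- min(i + block_size - 1L, n)
            res <- apply_filter(filt, out$samples[i:j], st)
            y[i:j] <- res$signal
            st <- res$state
            i <- j + 1L
        }
        out <- audio_signal(y, sr)
    }

    attr(out, "events") <- events
    attr(out, "log") <- list(config = spec_to_config(spec), seed = seed,
                             block_size = block_size,
                             latency_samples = engine_latency(config),
                             n_onsets = length(events))
    out
}
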