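# The four atomic audio effects: constant pitch shift (a scalar ratio),
# vibrato and inflection (per-sample ratio tracks for the harmonizer), and
# shelving filters (signal-domain IIR).

#' Vibrato parameters
#'
#' Vibrato is a sinusoidal modulation of the pitch-shift factor with a rate
#' (modulation frequency, Hz), a depth (cents) and a random variation of the
#' rate expressed as a fraction of the rate (0.30 = 30%). The instantaneous
#' rate is re-drawn uniformly in `rate * (1 +/- rate_jitter)` once per
#' modulation cycle, keeping the phase continuous across cycle boundaries.
#'
#' @param rate Modulation rate in Hz (> 0).
#' @param depth Modulation depth in cents (>= 0).
#' @param rate_jitter Random rate variation as a fraction of `rate`
#'   (in \[0, 1)).
#' @return An object of class `"vibrato_params"`.
#' @export
vibrato_params <- function(rate = 8.5, depth = 40, rate_jitter = 0.30) {
    if (rate <= 0) stop("rate must be > 0", call. = FALSE)
    if (depth < 0) stop("depth must be >= 0", call. = FALSE)
    if (rate_jitter < 0 || rate_jitter >= 1)
        stop("rate_jitter must be in [0, 1)", call. = FALSE)
    structure(list(rate = rate, depth = depth, rate_jitter = rate_jitter),
              class = "vibrato_params")
}

#' Generate a vibrato ratio track
#'
#' With `rate_jitter = 0` the cents track is exactly
#' `depth * sin(2*pi*rate*t)`; with jitter, each modulation cycle runs at a
#' frequency drawn uniformly in `rate * (1 +/- rate_jitter)` (deterministic
#' given `seed`), with continuous phase.
#'
#' @param params A [vibrato_params()].
#' @param n_samples Track length in samples.
#' @param sample_rate Sampling rate in Hz.
#' @param seed RNG seed for the per-cycle rate draws.
#' @return Per-sample pitch ratio sequence (length `n_samples`).
#' @export
vibrato_track <- function(params, n_samples, sample_rate, seed = 0L) {
    stopifnot(inherits(params, "vibrato_params"), n_samples >= 0)
    n_samples <- as.integer(n_samples)
    if (n_samples == 0L) return(numeric(0))
    t <- (seq_len(n_samples) - 1L) / sample_rate
    if (params$depth == 0) return(rep(1, n_samples))
    if (params$rate_jitter == 0) {
        cents <- params$depth * sin(2 * pi * params$rate * t)
        return(cents_to_ratio(cents))
    }
    dur <- n_samples / sample_rate
    n_cycles <- ceiling(dur * params$rate / (1 - params$rate_jitter)) + 8L
    f <- with_seed(seed, runif(n_cycles,
                               params$rate * (1 - params$rate_jitter),
                               params$rate * (1 + params$rate_jitter)))
    bounds <- cumsum(c(0, 1 / f))            # cycle start times
    k <- findInterval(t, bounds)             # cycle index per sample (>= 1)
    phase <- 2 * pi * ((k - 1) + f[k] * (t - bounds[k]))
    cents_to_ratio(params$depth * sin(phase))
}

#' Inflection parameters
#'
#' Inflection is a rapid (~500 ms) pitch excursion applied from each detected
#' utterance onset. Two profile shapes are provided: `"happy_rise"` starts at
#' `min_cents`, rises quickly to `max_cents` (first 25% of the duration) and
#' releases back to the original pitch by the end of the duration;
#' `"afraid_sinusoid"` starts at `max_cents` and oscillates within the bounds
#' while decaying to zero. Onsets are detected from causal sliding-window RMS
#' crossing a threshold, with a re-arm condition so one utterance fires once.
#'
#' @param profile_shape `"happy_rise"` or `"afraid_sinusoid"`.
#' @param duration_ms Profile duration in ms (> 0).
#' @param min_cents,max_cents Minimum/maximum pitch shift of the profile in
#'   cents (`min_cents <= max_cents`).
#' @param rms_window_ms Causal RMS analysis window in ms.
#' @param rms_threshold_dbfs Attack threshold in dBFS.
#' @param rearm_dbfs RMS must fall below this level to re-arm the detector.
#' @param rearm_gap_ms ... for at least this long (ms).
#' @return An object of class `"inflection_params"`.
#' @export
inflection_params <- function(profile_shape = c("happy_rise", "afraid_sinusoid"),
                              duration_ms = 500,
                              min_cents = -200, max_cents = 140,
                              rms_window_ms = 20,
                              rms_threshold_dbfs = -40,
                              rearm_dbfs = -50,
                              rearm_gap_ms = 200) {
    profile_shape <- match.arg(profile_shape)
    if (duration_ms <= 0) stop("duration_ms must be > 0", call. = FALSE)
    if (min_cents > max_cents) stop("min_cents must be <= max_cents", call. = FALSE)
    if (rms_window_ms <= 0) stop("rms_window_ms must be > 0", call. = FALSE)
    structure(list(profile_shape = profile_shape, duration_ms = duration_ms,
                   min_cents = min_cents, max_cents = max_cents,
                   rms_window_ms = rms_window_ms,
                   rms_threshold_dbfs = rms_threshold_dbfs,
                   rearm_dbfs = rearm_dbfs, rearm_gap_ms = rearm_gap_ms),
              class = "inflection_params")
}

#' An utterance-onset event
#' @param onset_time Onset time in seconds (>= 0).
#' @param params The [inflection_params()] applied from this onset.
#' @return An object of class `"inflection_event"`.
#' @export
inflection_event <- function(onset_time, params) {
    stopifnot(onset_time >= 0, inherits(params, "inflection_params"))
    structure(list(onset_time = onset_time, params = params),
              class = "inflection_event")
}

#' Detect utterance onsets from sliding-window RMS
#'
#' Causal: the RMS at time t uses only samples at or before t (zero-padded
#' before the signal start). An event fires at each up-crossing of
#' `rms_threshold_dbfs`; no further event fires until the RMS has stayed
#' below `rearm_dbfs` for at least `rearm_gap_ms`.
#'
#' @param signal An [audio_signal()].
#' @param params An [inflection_params()].
#' @return A list of [inflection_event()]s (empty for silence).
#' @export
detect_onsets <- function(signal, params) {
    stopifnot(inherits(signal, "audio_signal"),
              inherits(params, "inflection_params"))
    x <- signal$samples
    n <- length(x)
    if (n == 0L) return(list())
    sr <- signal$sample_rate
    w <- max(1L, as.integer(round(params$rms_window_ms / 1000 * sr)))
    gap <- max(1L, as.integer(round(params$rearm_gap_ms / 1000 * sr)))

    cs <- cumsum(x ^ 2)
    head_n <- seq_len(min(w, n))
    energy <- c(cs[head_n] / w, if (n > w) (cs[(w + 1L):n] - cs[seq_len(n - w)]) / w)
    rms <- sqrt(energy)

    thr <- 10 ^ (params$rms_threshold_dbfs / 20)
    rearm <- 10 ^ (params$rearm_dbfs / 20)

    above <- rms >= thr
    ups <- which(above & !c(FALSE, above[-n]))          # up-crossing samples
    if (length(ups) == 0L) return(list())

    # rearm_ok[m]: TRUE if rms < rearm for the `gap` samples ending at m
    below <- rms < rearm
    cb <- cumsum(below)
    rearm_ok <- rep(FALSE, n)
    if (n >= gap)
        rearm_ok[gap:n] <- (cb[gap:n] - c(0, cb)[(gap:n) - gap + 1L]) == gap

    events <- list()
    i <- ups[1L]
    repeat {
        events[[length(events) + 1L]] <-
            inflection_event((i - 1L) / sr, params)
        m <- which(rearm_ok & seq_len(n) > i)
        if (length(m) == 0L) break
        nxt <- ups[ups > m[1L]]
        if (length(nxt) == 0L) break
        i <- nxt[1L]
    }
    events
}

# Profile value in cents at normalized time s in [0, 1).
# happy_rise: linear rise min -> max over the first quarter, then a
# square-root raised-cosine release max*sqrt(cos(pi/2 * u)) so the excursion
# keeps a perceptible deviation for the full profile duration and reaches the
# original pitch exactly at the terminal boundary ("recedes after" the stated
# duration, not before).
# afraid_sinusoid: max*cos(2*pi*s)*(1 - s), starting at the maximum and
# decaying to zero while oscillating within the bounds.
inflection_profile_cents <- function(s, params) {
    out <- numeric(length(s))
    inside <- s >= 0 & s < 1
    si <- s[inside]
    if (params$profile_shape == "happy_rise") {
        rise_frac <- 0.25
        v <- ifelse(si < rise_frac,
                    params$min_cents +
                        (params$max_cents - params$min_cents) * si / rise_frac,
                    params$max_cents *
                        sqrt(cos(pi / 2 * (si - rise_frac) / (1 - rise_frac))))
    } else {
        v <- params$max_cents * cos(2 * pi * si) * (1 - si)
    }
    out[inside] <- v
    out
}

#' Build the inflection ratio track for a set of onset events
#'
#' The cents profile of each event occupies `[onset, onset + duration)` and
#' is exactly zero elsewhere; where event windows overlap, the later event
#' replaces the earlier one.
#'
#' @param events List of [inflection_event()]s (causally ordered).
#' @param n_samples Track length in samples.
#' @param sample_rate Sampling rate in Hz.
#' @return Per-sample pitch ratio sequence.
#' @export
inflection_track <- function(events, n_samples, sample_rate) {
    n_samples <- as.integer(n_samples)
    cents <- numeric(n_samples)
    if (n_samples == 0L) return(numeric(0))
    t <- (seq_len(n_samples) - 1L) / sample_rate
    for (ev in events) {
        stopifnot(inherits(ev, "inflection_event"))
        dur <- ev$params$duration_ms / 1000
        s <- (t - ev$onset_time) / dur
        idx <- which(s >= 0 & s < 1)
        if (length(idx))
            cents[idx] <- inflection_profile_cents(s[idx], ev$params)
    }
    cents_to_ratio(cents)
}

#' Shelving-filter parameters
#'
#' `kind = "high_shelf"` leaves the band below the cutoff flat (0 dB) and
#' boosts above it; `kind = "low_shelf"` (the "darker" variant) leaves the
#' low band flat and attenuates toward and above the cutoff. The slope is
#' the normative, measurable contract: the magnitude-gain difference across
#' one octave at the cutoff (`|H|dB(2 fc) - |H|dB(fc)` for a high shelf,
#' `|H|dB(fc) - |H|dB(fc/2)` for a low shelf) equals `slope` dB.
#'
#' @param kind `"high_shelf"` or `"low_shelf"`.
#' @param cutoff Cutoff frequency in Hz.
#' @param slope Octave slope in dB (positive for a boosting high shelf,
#'   negative for an attenuating low shelf).
#' @param order Filter order (default 5).
#' @return An object of class `"shelf_params"`.
#' @export
shelf_params <- function(kind = c("high_shelf", "low_shelf"), cutoff, slope,
                         order = 5L) {
    kind <- match.arg(kind)
    if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
    if (order < 1L) stop("order must be >= 1", call. = FALSE)
    structure(list(kind = kind, cutoff = cutoff, slope = slope,
                   order = as.integer(order)),
              class = "shelf_params")
}

# Butterworth-pattern pole positions on the unit circle (left half-plane).
butterworth_pattern <- function(n) {
    k <- seq_len(n)
    exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Digital shelf from an analog pole/zero prototype: zeros at wc/r * pattern,
# poles at wc*r * pattern (wc prewarped), bilinear-transformed, gain fixed
# for exactly 0 dB at DC. r > 1 boosts the high band by r^(2*order) (in
# amplitude), r < 1 attenuates it; r is the transition-spread knob solved
# against the octave-slope contract by design_shelf().
shelf_zpk_digital <- function(r, cutoff, order, sample_rate) {
    wc <- 2 * sample_rate * tan(pi * cutoff / sample_rate)  # prewarped
    pat <- butterworth_pattern(order)
    sz <- wc / r * pat
    sp <- wc * r * pat
    f2 <- 2 * sample_rate
    zd <- (1 + sz / f2) / (1 - sz / f2)
    pd <- (1 + sp / f2) / (1 - sp / f2)
    b <- Re(poly_from_roots(zd))
    a <- Re(poly_from_roots(pd))
    g <- sum(a) / sum(b)                                    # unity at DC
    list(b = b * g, a = a)
}

# Monic polynomial coefficients (descending powers... here: b[1] + b[2] z^-1
# + ...; we build in z^-1 form from roots of z) from complex roots.
poly_from_roots <- function(r) {
    coef <- 1
    for (rt in r) coef <- c(coef, 0) - c(0, coef * rt)
    coef
}

# Complex frequency response of a b/a coefficient set at frequencies f (Hz).
filter_response <- function(coeffs, f, sample_rate) {
    w <- 2 * pi * f / sample_rate
    num <- vapply(w, function(wi)
        sum(coeffs$b * exp(-1i * wi * (seq_along(coeffs$b) - 1))), complex(1))
    den <- vapply(w, function(wi)
        sum(coeffs$a * exp(-1i * wi * (seq_along(coeffs$a) - 1))), complex(1))
    num / den
}

octave_gain_diff <- function(coeffs, cutoff, kind, sample_rate) {
    f <- if (kind == "high_shelf") c(cutoff, 2 * cutoff) else c(cutoff / 2, cutoff)
    h <- 20 * log10(Mod(filter_response(coeffs, f, sample_rate)))
    h[2] - h[1]
}

#' Design a Butterworth shelving filter
#'
#' Builds an order-`order` (default 5) Butterworth-pattern pole/zero shelf
#' via the bilinear transform (prewarped at the cutoff) and solves its
#' transition spread numerically so that the measured octave gain difference
#' at the cutoff equals `slope` exactly. The passband far from the cutoff
#' stays at 0 dB and all poles lie strictly inside the unit circle.
#'
#' @param params A [shelf_params()].
#' @param sample_rate Sampling rate in Hz (cutoff must be below Nyquist; for
#'   a high shelf the octave above the cutoff must also fit below Nyquist).
#' @return An object of class `"shelf_filter"`: list with coefficient vectors
#'   `b`, `a` (direct form, `a[1] = 1`) plus the design parameters.
#' @seealso [apply_filter()], [measure_filter_slope()]
#' @export
design_shelf <- function(params, sample_rate) {
    stopifnot(inherits(params, "shelf_params"))
    nyq <- sample_rate / 2
    if (params$cutoff >= nyq)
        stop("cutoff must be below the Nyquist frequency", call. = FALSE)
    fhi <- if (params$kind == "high_shelf") 2 * params$cutoff else params$cutoff
    if (fhi >= nyq)
        stop("the measurement octave must lie below Nyquist", call. = FALSE)

    if (params$slope == 0) {
        coeffs <- list(b = 1, a = 1)
    } else {
        target <- if (params$kind == "high_shelf") params$slope else params$slope
        slope_of <- function(r)
            octave_gain_diff(shelf_zpk_digital(r, params$cutoff, params$order,
                                               sample_rate),
                             params$cutoff, params$kind, sample_rate) - target
        interval <- if (target > 0) c(1 + 1e-9, 8) else c(1 / 8, 1 - 1e-9)
        r <- uniroot(slope_of, interval, tol = 1e-12)$root
        coeffs <- shelf_zpk_digital(r, params$cutoff, params$order, sample_rate)
        coeffs$r <- r
    }
    structure(c(coeffs,
                list(kind = params$kind, cutoff = params$cutoff,
                     slope = params$slope, order = params$order,
                     sample_rate = sample_rate)),
              class = "shelf_filter")
}

#' Fresh state for block-wise IIR filtering
#' @param filt A `"shelf_filter"` (or any list with `b`, `a`).
#' @return Numeric state vector of length `max(length(b), length(a)) - 1`.
#' @export
filter_state <- function(filt) {
    numeric(max(length(filt$b), length(filt$a)) - 1L)
}

#' Apply an IIR filter block-wise with carried state
#'
#' Direct-form II transposed; applying a signal split into blocks with the
#' returned state carried between calls is bit-identical to one whole-signal
#' call.
#'
#' @param filt A `"shelf_filter"` coefficient set.
#' @param signal An [audio_signal()] (or numeric block).
#' @param state State vector from [filter_state()] (or a previous call);
#'   `NULL` starts from rest.
#' @return List with elements `signal` (filtered [audio_signal()]) and
#'   `state` (to pass to the next block).
#' @export
apply_filter <- function(filt, signal, state = NULL) {
    x <- if (inherits(signal, "audio_signal")) signal$samples else as.numeric(signal)
    if (is.null(state)) state <- filter_state(filt)
    if (length(state) != max(length(filt$b), length(filt$a)) - 1L)
        stop("filter state dimension does not match the coefficient set",
             call. = FALSE)
    st <- as.numeric(state) + 0   # private copy: the C loop updates in place
    y <- .iir_df2t_cpp(as.numeric(filt$b), as.numeric(filt$a), x, st)
    out <- if (inherits(signal, "audio_signal"))
        audio_signal(y, signal$sample_rate) else y
    list(signal = out, state = st)
}
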