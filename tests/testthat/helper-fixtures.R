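# Shared helpers for the suite: all fixtures are generated in code.

SR <- 44100

# Engine group delay at the default window: half the (even) tap wrap modulus.
engine_delay_samples <- function(config = engine_config()) {
    2 * (engine_latency(config) %/% 2L) / 2L
}

# Compare an engine output against the delay-compensated input.
delay_compensated_equal <- function(out, input, delay = engine_delay_samples()) {
    n <- length(input$samples)
    identical(out$samples[(delay + 1L):n], input$samples[1L:(n - delay)])
}

# Oracle measurement of a constant shift, in cents: each signal is tracked
# with a search range bracketing its expected pitch (the measurement
# protocol for a known-target transposition check).
measured_shift_cents <- function(input, output, f_in, shift_cents) {
    f_out <- f_in * cents_to_ratio(shift_cents)
    t_in <- track_pitch(input, fmin = 0.7 * f_in, fmax = 1.4 * f_in)
    t_out <- track_pitch(output, fmin = 0.7 * f_out, fmax = 1.4 * f_out)
    1200 * log2(median_f0(t_out) / median_f0(t_in))
}

# A standard sustained-vowel fixture.
vowel_fixture <- function(f0 = 220, dur = 2, sr = SR)
    make_vowel(fixture_spec(f0 = f0, duration = dur, sample_rate = sr))
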