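---
title: "Methods: causal emotional voice transformation and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal emotional voice transformation and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emovox` implements a small family of causal, low-latency audio effects
that, combined, make a neutral voice sound happy, sad or afraid, together
with the measurement machinery needed to verify — on synthetic signals
with known ground truth — that each transformation does acoustically what
its parameters claim. This vignette is the package's own account of the
models, the defaults, and the design decisions that were genuinely open.

## The processing model

All pitch manipulation rides on one engine: a **harmonizer**, i.e. a
delay line whose read tap moves. If the tap delay d(n) changes by
(1 − α) samples per sample, the read pointer advances at rate α relative
to the write pointer and the output is the input transposed by the factor
α = 2^(cents/1200). Because the delay must stay inside a finite window
(`max_delay`, default 10 ms), the tap wraps; a second tap placed half a
wrap period behind takes over across each wrap. The handover uses a
raised-cosine crossfade confined to 12.5% of the wrap period on either
side of a tap's wrap point, with complementary gains that sum to exactly
one. Outside the fades a single tap is heard at gain exactly 1.

Two consequences of this realization are load-bearing:

* **Latency.** The engine's only delay is the window: the algorithmic
  latency is `round(max_delay * sample_rate)` samples (441 at 44.1 kHz),
  and the resting tap sits at half the wrap modulus, so a unity-ratio
  transform is a constant ~5-ms delay. The suite measures this by
  cross-correlating a band-limited click train with its unity transform.
* **Bit-exact identity.** The wrap modulus is rounded down to an *even*
  number of samples (440 at 44.1 kHz) so the resting tap delay (220) is an
  integer and its gain exactly 1. With ratio 1 the output is then a pure
  integer delay — bit-identical to the input after compensation — which
  makes "the neutral preset does nothing" a falsifiable, exact test
  rather than an SNR threshold. With an odd modulus the resting tap would
  sit between samples and linear interpolation would smear one LSB of
  error over every sample.

Fractional delays are linearly interpolated. For the subtle shifts this
package targets (presets stay within ±200 cents) linear interpolation's
high-frequency roll-off at non-integer delays is far below the shelving
filters' intentional spectral shaping; a cubic interpolator was
considered and rejected as complexity without a measurable benefit at
these shift sizes. Ratios outside [0.5, 2] are refused: beyond an octave
the tap drift rate makes wrap periods so short that the crossfade
dominates the output, and the presets never approach that regime.

Vibrato and inflection do not get their own engines. Each effect emits a
per-sample *cents profile*; profiles are accumulated by multiplying their
ratio tracks (equivalently, summing cents), and the single product track
drives the harmonizer once. The shelving filter is applied after the
pitch stage, so the spectral shaping is imposed on the final spectrum
rather than being transposed along with it.

### Vibrato

A sinusoidal modulation of the pitch factor with rate (Hz), depth
(cents), and a random rate variation expressed as a fraction of the rate.
The randomness model is: at each completed modulation cycle the
instantaneous frequency is re-drawn uniformly in `rate * (1 ± jitter)`,
with phase kept continuous. A per-cycle re-draw keeps the track periodic
at the short scale (each cycle is a clean sinusoid) while decorrelating
cycle lengths, which is what "X% random rate variation" plausibly means
for a modulation generator; nothing in the validated parameterization
constrains the distribution further, so uniform was chosen and frozen.
With jitter 0 the implementation takes a separate exact path,
`depth * sin(2*pi*rate*t)`, so calibration tests assert an identity, not
a tolerance. The modulator runs from stream start (not onset-gated) —
vibrato in natural voice is continuous through an utterance.

### Inflection

A transient pitch excursion at each utterance onset. Onsets are detected
causally: sliding-window RMS (window 20 ms) crossing a threshold
(−40 dBFS) fires an event; the detector re-arms only after the RMS has
stayed below −50 dBFS for 200 ms. Those four defaults are not part of
the validated parameter set — they were chosen once so that the detector
fires exactly once per utterance on speech-level signals (vowel fixtures
peak at 0.8, RMS well above −40 dBFS; inter-utterance silence is exact
zero) and were not revisited. An onset at time t uses only samples ≤ t,
so block-wise and whole-file runs see identical events.

Two profile shapes are provided, parameterized by duration (500 ms in all
presets), a minimum and a maximum shift in cents:

* **happy_rise** starts at `min` (−200 cents at nominal level), rises
  linearly to `max` (+140) over the first quarter of the duration, then
  releases as `max * sqrt(cos(pi/2 * s))` over the remaining three
  quarters. Only the endpoints, the peak and the total duration are
  fixed by the validated parameterization; the rise/release shapes were
  open. The square-root-cosine release was chosen because it keeps the
  excursion perceptibly away from zero (> 1 cent) for essentially the
  full stated duration and reaches zero exactly at the boundary — the
  inflection *recedes after* 500 ms rather than fading out early — while
  remaining monotone and click-free (the terminal step is below one
  cent).
* **afraid_sinusoid** is `max * cos(2*pi*s) * (1 - s)`: it starts at its
  maximum, oscillates within the bounds, and decays to zero by the end.
  The validated description fixes the bounds, the start-at-maximum and
  the decay but not the cycle count; one full cycle with a linear decay
  envelope is the simplest curve meeting all of it.

Overlapping events are resolved by letting the later event replace the
earlier — an utterance onset restarts the gesture, which is what a
listener expects of an onset-locked effect.

### Shelving filters

The presets specify shelf filters by cutoff (8000 Hz) and a slope in
dB/octave — a nonstandard parameterization for a shelf, so the package
treats the measurable statement as normative: the magnitude gain
difference across the octave at the cutoff (`|H|(2fc) − |H|(fc)` for the
high shelf; `|H|(fc) − |H|(fc/2)` for the low shelf) must equal the
preset slope. The "low shelf" of the sad preset keeps the band *below*
8 kHz as its 0-dB passband and attenuates toward and above the cutoff
(the "darker" voice), mirroring the happy high shelf's boost above it.

A parallel unity-plus-weighted-Butterworth realization was tried first
and discarded: near the cutoff the 5th-order path's phase rotates by
several radians, the complex sum is non-monotone in the path gain, and
for the −12 dB/octave target the octave-slope equation has no solution.
Instead the shelf is a pole/zero design: zeros on the Butterworth pattern
scaled by wc/r, poles scaled by wc·r (wc prewarped, bilinear transform),
overall gain pinned to exactly 0 dB at DC. The analog magnitude is then
`sqrt((w^10 + wz^10)/(w^10 + wp^10))` — monotone, flat far from cutoff,
with total shelf gain r^10 — and the single knob r is solved with
`uniroot` (tolerance 1e−12) directly on the *digital* octave-gain
difference, so the contract holds exactly at the design rate, not just in
the analog prototype. Stability is inherited from left-half-plane poles.
The suite checks pole radii and passband flatness at 16/44.1/48 kHz and
verifies the impulse response against the transfer function to 1e−6.

## Presets

The registry stores the validated parameter grid verbatim: three
emotions × three intensity levels ("high" is the nominal, strongest
validated setting), with gender-specific values only where the validation
used them (the afraid vibrato depth and inflection bounds). Happy and sad
ignore gender. A caller who cannot supply gender gets the male parameter
set with an explicit warning rather than a hard failure, so batch jobs
degrade loudly but not fatally. Only the nine printed parameter points
are supported; no interpolated intensity levels are generated, because
whether the validated level spacing was linear in the parameters or in
perception is unknowable from the parameter table alone.

## The evaluation layer

The point of the evaluation module is independence: nothing in it shares
code with the synthesis path.

* **Pitch oracle.** A YIN-style tracker: per frame, the difference
  function over a fixed integration window (computed by FFT
  cross-correlation), cumulative-mean normalization, an absolute
  threshold of 0.1 with fallback to the global minimum, and parabolic
  interpolation of the raw difference minimum. Frame hop is 10 ms; the
  integration window is one maximum lag (`fs/fmin`), so the frame is
  `2*fs/fmin`. Frames below −60 dBFS, or with no normalized minimum
  under 0.5, are unvoiced. On pure tones from 80–1000 Hz the tracker is
  well inside ±2 cents. One practical note baked into the test protocol:
  the frame length follows `fmin`, and long frames average over more of
  the harmonizer's crossfade flutter, so measurements of a *known*
  target pitch bracket the expected value (e.g. `fmin = 0.7*f`,
  `fmax = 1.4*f`) the way any measurement protocol narrows its
  instrument to the expected range.
* **Modulation analysis.** The voiced run of a pitch track is converted
  to cents about its log-mean, Hann-windowed, zero-padded 8×, and the
  dominant component above 2 Hz located by FFT; the frequency is then
  refined by maximizing the explained energy of a least-squares sinusoid
  fit, and the depth is that fit's amplitude. The LS amplitude avoids
  the window's coherent-gain bias at non-integer cycle counts.
* **Filter measurement** evaluates the designed transfer function
  directly at the contract frequencies (after a stability check on the
  pole radii), so filter verification and filter design share only the
  coefficient set.
* **Recognition statistics.** For a forced-choice confusion table with
  diagonal count a, row total r, column total c and grand total N:
  `H_u = a²/(r·c)` (sensitivity × specificity), `p_c = r·c/N²`, raw hit
  rate `a/r`, and the proportion index `pi = p(k−1)/(1 + p(k−2))`
  (chance 1/k ↦ 0.5, perfect ↦ 1; depends only on p and k, hence
  invariant to relabeling non-target options). Paired comparisons use
  `asin(sqrt(x))`-transformed values in a paired t test
  (df = n − 1), with Holm–Bonferroni adjustment across a supplied
  family. A degenerate paired sample with zero-variance differences
  returns t = 0 (mean difference 0) rather than erroring, so identical
  inputs are a well-defined fixture. With five response alternatives,
  k = 5 throughout. Published per-participant data are not available, so
  published t values are not recomputable; the machinery is instead
  validated by its exact hand-computable cases and by a Monte-Carlo
  type-I error check (5000 replicates of 20 null pairs) in the suite.

## The fixture generator

Synthetic vowels stand in for recorded speech: a band-limited pulse
train (harmonics to 90% of Nyquist, 1/k roll-off — a crude glottal
spectrum) through three second-order formant resonators at /a/-like
values (700/130, 1220/70, 2600/160 Hz), gated to utterance intervals
with 5-ms raised-cosine edges and *exact* zeros between utterances, then
peak-normalized (default 0.8). The generator emulates what the contracts
need: a strong, harmonically rich f0; formant structure so the pitch
oracle faces a speech-like (not sinusoidal) spectrum; and utterance
boundaries with known ground truth for the onset detector. It does not
emulate jitter/shimmer, breath noise, coarticulation, or prosodic f0
movement — so passing tests demonstrate parameter fidelity of the
effects, not perceptual validity on natural speech, which is exactly the
division of labor in the original validation (acoustic contracts by
measurement, perceptual validity by human raters).

## Numerical choices and degenerate inputs

* All internal audio is double precision; quantization happens only in
  `write_wav` (16/24-bit PCM with clipping, or float32).
* Streaming equivalence is exact by construction: the engine and the
  IIR filters carry explicit state through identical per-sample
  arithmetic, so any block partition is bit-identical to a whole-file
  run; the suite asserts `identical()`, not a tolerance, for every
  preset on a 5-s fixture.
* Digital silence: peak normalization warns and no-ops; the onset
  detector returns no events; the pitch tracker returns all-unvoiced.
* Problem sizes in the suite were chosen to keep the full run around
  ten seconds while leaving every measurement at least ~20 modulation
  or pitch cycles: 1–5-s fixtures at 44.1 kHz, 200 random confusion
  tables, 5000 Monte-Carlo replicates.

## Known limitations

* The harmonizer's crossfade handovers blend two copies of the signal
  with different phase offsets; during a fade the instantaneous
  frequency wobbles. The localized fade keeps a single tap solo 75% of
  the time so median-based pitch measurements are unaffected, but the
  flutter exists in the waveform, as it does in any dual-tap
  harmonizer.
* Stereo, live device I/O, codecs other than WAV, formant or
  speech-rate manipulation are out of scope; the latency contract is
  verified by cross-correlation, not against audio hardware.
* The preset cutoff of 8 kHz requires a sample rate comfortably above
  16 kHz; at lower rates the design refuses (cutoff or its measurement
  octave would cross Nyquist) rather than silently detuning.
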