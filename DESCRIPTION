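Package: emovox
Title: Real-Time Emotional Voice Transformation and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal, low-latency audio effects for emotional voice
    transformation: delay-line (harmonizer) pitch shifting, vibrato,
    utterance-onset pitch inflection, and Butterworth shelving filters,
    combined into validated happy/sad/afraid presets at three intensity
    levels. Includes a synthetic voice fixture generator, an independent
    YIN-style pitch-tracking oracle, modulation and filter-response
    measurement, and chance-corrected forced-choice recognition statistics
    (unbiased hit rate, individual chance proportion, proportion index,
    arcsine-transformed paired comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
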