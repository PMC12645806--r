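Package: regmem
Title: Ideal-Observer Models and Sustained-Response Analysis for Auditory Regularity Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how memory for past auditory input shapes the
    inferred predictability of unfolding tone-pip sequences. Generates the
    symbolic tone sequences (regular patterns, pattern transitions, and brief
    random interruptions) used in passive-listening EEG paradigms, implements a
    variable-order Markov model with prediction-by-partial-matching (PPM)
    smoothing to compute per-tone information content under observer variants
    with different memory spans (including a memory-reset observer), simulates
    multichannel EEG epochs with planted sustained, onset, and deviance
    components, and provides the accompanying analysis chain: zero-phase
    Butterworth filtering, detrending, baseline correction, denoising source
    separation (DSS), auditory channel selection, RMS summaries, and
    group-level bootstrap statistics with split-half cluster-duration null
    distributions and recovery-latency estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
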