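Package: gazesync
Title: Dual-EEG Analysis of Inter-Brain Synchrony Around Naturalistic Gaze
    Onsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for dual-EEG (hyperscanning) studies of naturalistic
    infant-caregiver interaction. Simulates dyadic gaze behaviour and
    synchronized two-person EEG with controllable ground truth (ERP
    templates, oscillatory phase resets, inter-brain coupling, ocular
    artifacts); provides deterministic preprocessing (zero-phase band-pass
    filtering, robust average referencing, correlation-based channel
    interpolation, high-power segment rejection, event epoching and
    gaze-state segmentation); complex Morlet time-frequency decomposition;
    phase locking value, partial directed coherence over BIC-selected
    vector autoregressive models, and inter-trial coherence; surrogate
    dyad-pairing and random-event null distributions, cluster-based
    permutation tests, two-way repeated-measures ANOVA with Tukey-Kramer
    correction, JZS Bayes factors and paired-t power calculations; and
    cohort-level pipelines for non-event-locked, event-locked inter-brain
    and intra-brain analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
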