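Package: cmcbursts
Title: Corticomuscular Coherence and Beta-Burst Analysis for Gripper-Task MEG/EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for corticomuscular coherence (CMC) and
    cortical beta-burst dynamics in epoched MEG/EMG gripper-task recordings.
    Provides multitaper magnitude-squared coherence on the 8-40 Hz grid,
    Morlet wavelet beta-power time courses, Hilbert-envelope beta-burst
    detection with fractional occupancy, duration and amplitude metrics,
    behavioural metrics from grip-force channels, cluster-based permutation
    tests over time and frequency, and permutation GLMs with maximum-t
    family-wise error correction and confound regressors. A synthetic
    two-group cohort generator with known burst and coupling ground truth
    makes every stage verifiable without human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
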