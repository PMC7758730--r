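Package: cortexstate
Title: Cortical State Analysis for Widefield Calcium Imaging During Decision-Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cortical synchronization state from dual-channel
    widefield calcium imaging during head-fixed decision-making tasks. Movies are
    held in SVD-compressed form and all spectral analysis runs in the compressed
    domain: per-pixel 3-6 Hz band power maps, condition-difference maps in
    decibels, hemodynamic artifact removal by per-pixel regression on a
    calcium-independent channel, trial classification and quiescent-window
    extraction, power-percentile behavioral curves, reaction-time residual
    correlations, pupil ANCOVA, nested mixed-effects contrasts, spike/LFP state
    measures (multiunit binning, Fano factor, coherence, cross-frequency power
    correlation, spike-prediction filters), and trial-equalized population
    decoding of stimulus presence. A seeded synthetic-session generator with
    ground truth makes every stage verifiable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmnet,
    rhdf5,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
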