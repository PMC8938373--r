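Package: nbackerp
Title: Working-Memory N-Back EEG/ERP Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for P300 event-related
    potentials in adaptive n-back working-memory studies. Provides an
    adaptive n-back staircase and EEG sequence generator with placement
    constraints, a synthetic-cohort and continuous-EEG generator with
    known ground truth, deterministic preprocessing (re-referencing,
    zero-phase filtering, resampling, epoching, baseline correction),
    ICA-based ocular artifact removal with z-scored component suspect
    scoring and bad-channel interpolation montages, P300 window-mean
    amplitude and fractional-area latency measurement over parietal and
    frontal regions of interest, and the matching statistical layer:
    mixed factorial ANCOVA with an age covariate and a
    homogeneity-of-regression gate, partial eta squared, Fisher r-to-z
    between-group correlation comparison, Benjamini-Hochberg FDR,
    linear-versus-quadratic AICc model comparison, and Kaplan-Meier /
    log-rank analysis of achieved n-back level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    survival,
    car,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
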