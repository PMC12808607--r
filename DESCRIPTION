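Package: pharmfc
Title: Time-Resolved Functional Connectivity Analysis for Pharmacological fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pharmacological resting-state fMRI
    experiments in which a drug challenge is delivered mid-acquisition.
    Implements interval-based static functional connectivity (Pearson
    correlation with Fisher z transformation), sliding-window dynamic
    connectivity with per-region global-connectivity aggregation, a paired
    drug-versus-terminal-interval edge contrast with Benjamini-Hochberg
    false-discovery-rate correction and injection-artifact exclusion, group
    independent component analysis of concatenated runs with Welch power
    spectral density and slow-band (slow-5/4/3) power statistics, and a
    synthetic multi-region BOLD generator with known genotype-conditional
    connectivity and spectral ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
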