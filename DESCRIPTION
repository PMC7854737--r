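Package: rdfc
Title: Recursive Dynamic Functional Connectivity for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes recursive dynamic functional connectivity (rdFC) patterns
    from multichannel EEG: sliding-window Pearson correlation applied
    recursively to electrode triplets, yielding five orders of static
    connectivity summarised as a 5-point pattern in 3D correlation space.
    Includes a scale- and translation-invariant direction-cosine match score
    for comparing patterns against reference sets, Monte-Carlo calibration of
    the significance threshold, prevalence and prediction analyses over
    triplet permutations, temporal tracking of match scores across epochs,
    preictal/interictal reference comparison for seizure-linked transitions,
    EDF input/output, standard clinical preprocessing (zero-phase band-pass
    and notch filtering, re-referencing, resampling, epoch selection), and a
    synthetic trivariate signal generator with controllable coupling for
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
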