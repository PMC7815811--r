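Package: dynfc
Title: Sliding-Window Dynamic Functional Connectivity with Surrogate Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state dynamic functional connectivity (dFC)
    analysis of multi-region BOLD time series. Implements tapered
    sliding-window weighted Pearson correlation, two dFC variability
    statistics (summed successive difference and coefficient of variation),
    global and subnetwork summarisation with global normalisation,
    phase-randomization surrogate null testing that preserves static
    connectivity and autocorrelation, motion-based quality control,
    atlas-masked region time-series extraction from 4D images, clinical
    fatigue scoring (CIS-20r), normality-gated group comparisons, and
    hierarchical forward regression. Includes a synthetic-data generator
    producing cohorts of multi-region series with controlled static and
    time-varying correlation structure, motion traces, image fixtures, and
    clinical records, so the full pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
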