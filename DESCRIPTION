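Package: tgtforce
Type: Package
Title: Tension Gauge Tether Force-Response Analysis for B Cell Receptor Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative analysis of DNA tension gauge tether
    (TGT) force-sensor experiments on B cells imaged by total internal
    reflection fluorescence (TIRF) microscopy. Models the NP-TGT sensor panel
    (strand sequences, biotin-position to rupture-force map, rupture-force
    distributions), simulates ground-truthed single-molecule fields and
    immunological-synapse time-lapses, detects and fits diffraction-limited
    spots and microclusters with two-dimensional Gaussians, calibrates mean
    fluorescence intensity against molecular surface density with a
    through-origin regression, quantifies synaptic accumulation and contact
    area over time, and classifies multi-sensor force-response panels into
    statistically distinct activation levels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
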