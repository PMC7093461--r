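Package: lipidraft
Title: Lipidomic Identification, Quantification and NMR Ratio Profiling for
    Membrane Raft Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-detection LC-MS/MS lipidomics pipeline for comparing
    membrane microdomain (lipid raft versus non-raft) fractions, together
    with residue-resolved NMR intensity-ratio profiling. Identifies lipid
    molecular species against an in-silico spectral library by accurate
    precursor mass, weighted reverse dot-product MS/MS spectral similarity
    and trapezoidal retention-time similarity with dual score thresholds;
    converts accepted identifications to absolute amounts via per-subclass
    deuterated internal standards or an external calibration curve;
    aggregates species into subclass mol-percent compositions with
    two-group Student's t-test comparisons and acyl chain-length and
    saturation summaries; and computes normalized per-residue NMR
    intensity ratios and relative signal changes between conditions. A
    seeded synthetic-data generator produces libraries, two-group
    experiments, calibration levels and NMR peak tables with known ground
    truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
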