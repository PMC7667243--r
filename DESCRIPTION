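Package: pidotgate
Title: Manual and Automated Gating of PIDOT-Like Flow Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for comparing expert-style
    hierarchical Boolean gating against database-driven automated gating of
    blood lymphocyte populations measured with a PID Orientation tube
    (PIDOT)-like 14-parameter flow cytometry panel. Provides a synthetic
    sample generator with per-event ground-truth labels, FCS 3.0/3.1 and CSV
    input/output, a deterministic manual gating engine, an automated
    cluster-and-classify module with an annotated reference database and
    age-matched reference ranges, and the paired method-comparison statistics
    used in clinical method validation (percent differences, equivalence
    against the 20 percent criterion, clinical-relevance classification, and
    intra-/inter-observer reproducibility).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
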