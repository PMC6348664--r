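Package: rgstab
Title: Reference-Gene Stability Evaluation for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing stable reference (housekeeping) genes for
    RT-qPCR normalization. Implements the four stability statistics in
    common use - the comparative delta-Ct method, the geNorm M value with
    iterative gene elimination and pairwise variation, the NormFinder
    model-based stability value (grouped and ungrouped), and BestKeeper
    descriptive statistics - together with geometric-mean rank aggregation
    into a comprehensive ranking, amplification-efficiency estimation from
    dilution-series standard curves, and multi-reference-gene target
    normalization. A seeded generator of synthetic quantification-cycle
    (Ct) datasets with known per-gene instability provides ground truth
    for validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
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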