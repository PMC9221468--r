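Package: coDrugNet
Title: Consensus Co-Expression Modules and Drug-Response Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated drug mining for rare tumors from paired transcriptomes
    and high-throughput drug screens. Builds weighted gene co-expression
    networks for a cell-line and a tumor expression set, forms their consensus
    topological overlap, detects co-expression modules, and scores module
    preservation between the two datasets by a permutation Z-summary. Drug
    responses (area-under-curve viabilities) are correlated with the eigengenes
    of preserved modules to form per-drug fingerprints, drugs are grouped by
    resampling-based consensus clustering of their fingerprints, clinically
    advanced candidates are ranked, and two-drug combinations are predicted
    and scored under the independent-drug-action model over a trimmed
    concentration grid. A synthetic-data generator with planted modules,
    couplings and Hill dose-response curves provides ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
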