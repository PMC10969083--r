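Package: genefabric
Title: Genomic Fabric Analysis of Two-Condition Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes every quantified gene of a replicated two-condition
    expression experiment by its average expression level (AVE), relative
    expression variation (REV, a chi-square-corrected coefficient of
    variation), and pairwise expression correlations (COR), then derives
    relative expression control (REC), coordination degree (COORD), and gene
    commanding height (GCH). Regulation between conditions is called with a
    per-gene fold-change cut-off (CUT) computed from the gene's own REVs
    together with a heteroscedastic t-test, and summarized as weighted
    individual (WIR) and pathway (WPR) regulation. Intra- and inter-pathway
    coordination networks and their condition-to-condition remodeling are
    quantified and exported as edge lists. Includes a synthetic-data
    generator with block-structured correlations and known ground truth for
    validating every measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
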