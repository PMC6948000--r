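Package: ewasrep
Title: Cross-Ancestry Replication Analysis for Epigenome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("PURE", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess how well epigenome-wide association study (EWAS)
    findings replicate across cohorts and ancestries. Provides a synthetic
    methylation-cohort generator with planted trait effects, cell-mixture,
    slide-batch and hidden-confounder structure; detection p-value quality
    control; reference-based leukocyte cell-fraction deconvolution; per-CpG
    linear association models on beta values with surrogate-variable
    adjustment; confidence-interval-overlap replication classification with
    directional-consistency and genetic-context (mQTL/MAF) annotation;
    LMG relative-importance variance decomposition; Bonferroni thresholds and
    two-group power calculations; and a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
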