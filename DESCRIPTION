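Package: cndiscord
Title: Recurrent Copy-Number Loss Regions and Discordant Gene Upregulation
    in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates GISTIC2-thresholded copy-number calls with tumor and
    normal log2 expression matrices (UCSC Xena dialect) to call chromosomal
    regions of recurrent copy-number loss and identify the minority of genes
    within them that are nevertheless upregulated in tumor versus normal.
    Provides per-gene tumor/normal differential expression with tiered
    cut-offs, a contiguous-run loss-region caller with a tolerance rule and
    cross-cancer overlap rescue, hypergeometric overlap and local
    over-representation tests, common-essential four-bin and cumulative-rank
    comparisons, gene-set log2 fold-change summaries by copy-number bin, a
    synthetic-cohort generator with planted ground truth, and relative qPCR
    (2^dCt) quantification of tagged cell mixtures with exact Wilcoxon
    signed-rank testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
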