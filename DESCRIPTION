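Package: varkin
Title: Family-Exome Variant Prioritization for Mendelian Disease
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pedigree-aware prioritization of exome variants in nuclear
    families: quality-flag and homopolymer-adjacent indel filtering,
    population-frequency and coding-effect filters with a per-stage funnel
    report, Mendelian segregation models (de novo, autosomal recessive,
    X-linked recessive), ensemble deleteriousness majority voting and
    composite candidate ranking. Also provides induced protein-protein
    interaction network modules around seed genes, hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction, comparative-Ct
    qPCR quantification, dual-luciferase normalization and standard-curve
    calcium calibration, and a synthetic cohort generator with planted
    causal variants so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    igraph,
    optparse,
    stats,
    tools,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
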