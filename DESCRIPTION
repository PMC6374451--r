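Package: gcimpdemeth
Title: DNA Demethylation Analysis for IDH-Mutant Glioma Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis of DNA demethylation during malignant
    progression of IDH-mutant lower-grade gliomas. Provides readers and
    validators for Infinium 450K beta-value matrices, probe annotation,
    replication-timing bedGraph tracks, FPKM expression matrices and sample
    sheets; probe filtering, variance-based probe selection and ward.D2
    hierarchical clustering of methylation profiles; per-probe Welch
    differential methylation with Benjamini-Hochberg correction and
    CpG-context breakdown; replication-timing annotation with median-based
    late/intermediate/early categories and chi-square enrichment of
    demethylated probes in late-replicating domains; differential expression
    on FPKM; promoter methylation aggregation (top-25% most-different probe
    rule) with starburst methylation-expression integration and a per-probe
    promoter scan; fusion-junction read filtering; and a synthetic cohort
    generator with known ground truth that exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
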