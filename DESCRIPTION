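Package: methylink
Title: Integrated Whole-Genome Bisulfite Methylome and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline linking whole-genome bisulfite
    sequencing (WGBS) methylomes to matched gene expression tables in a
    two-group design. Provides strand-aware gene-region derivation (upstream /
    gene body / downstream with 3 kb flanks), weighted region methylation and
    metagene profiling stratified by expression class, rank-based methylation
    classes, a sliding-window pooled Fisher caller for differentially
    methylated regions with positional gene annotation, Welch-based
    differential expression with direction classes (group-specific and
    shifted), quadrant cross-tabulation of methylation and expression
    direction, region-wise Spearman correlation of methylation and
    expression, hypergeometric gene-set enrichment against user-supplied GMT
    files, and a beta-binomial synthetic-data generator that reproduces the
    statistical structure the analysis assumes (TSS methylation dip, high
    gene-body/downstream methylation, methylation-coupled expression,
    injected DMRs and DEGs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    IRanges,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
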