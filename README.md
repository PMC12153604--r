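# methylink

Integrated analysis of whole-genome bisulfite sequencing (WGBS) methylomes
and matched gene expression in a two-group design.

## The scientific problem

DNA methylation regulates transcription in a position-dependent way: promoter
methylation generally represses a gene, while gene-body methylation of
actively transcribed genes tends to be elevated. Studies that profile both a
WGBS methylome and an expression table for two phenotype groups (e.g. a
high-trait group `H` and a low-trait group `L`, a few biological replicates
each) need a common pipeline that

1. summarises methylation over strand-aware gene regions (upstream flank,
   gene body, downstream flank) and as a metagene profile around the
   transcription start site;
2. calls differentially methylated regions (DMRs) between the groups with a
   sliding-window pooled Fisher exact test;
3. calls differentially expressed genes (DEGs) with Welch's t-test on
   log-transformed RPKM and classifies their direction;
4. links DMRs to the genes whose regions contain them and quantifies the
   methylation–expression association: region-wise Spearman correlation,
   E±/M± quadrant tables, expression change by DMR direction, and
   hypergeometric gene-set enrichment.

`methylink` implements all of these stages as composable functions plus a
single `run_pipeline()` driver, and ships a deterministic synthetic-data
generator with ground-truth tables so that every stage can be tested for
calibration (no false signal under the null) and recovery (injected signal is
found). See the vignette
`vignettes/methylome-expression-integration.Rmd` for the methods.

## Worked example

Simulate a small dataset with known truth, then run the main analyses:

```r
library(methylink)
library(data.table)

cfg <- sim_config(seed = 42, n_genes = 120,
                  dmr_injection = list(n_dmrs = 15L, effect_size = 0.4, width = 600L),
                  deg_injection = list(n_degs = 25L, log2fc_effect = 2))
sim <- simulate_dataset(cfg)   # 120 genes, 4 H + 4 L samples, ~40k CpG sites

dmrs <- call_dmrs(sim$calls_H, sim$calls_L, contexts = "CG")
head(dmrs[order(p_value)], 4)
#>     chrom  start    end context   level_H   level_L diff_level       p_value direction n_sites
#> 1:   chr1 416250 416950      CG 0.5067732 0.8723028 -0.3655296 9.823186e-205        M-      23
#> 2:   chr1 475350 476250      CG 0.5343511 0.8301158 -0.2957647 8.873790e-181        M-      34
#> 3:   chr1 747300 748100      CG 0.3609375 0.7447130 -0.3837755 3.214831e-175        M-      21
#> 4:   chr1 441900 442550      CG 0.3539011 0.7565308 -0.4026298 2.465919e-144        M-      16

groups <- setNames(rep(c("H", "L"), each = 4), c(paste0("H", 1:4), paste0("L", 1:4)))
degs <- deg_table(sim$expression, groups)
table(degs$direction_class)
#>         none   other_down     other_up special_down
#>           93           11           15            1

rme <- region_methylation(pool_calls(rbind(sim$calls_H, sim$calls_L)),
                          gene_regions(sim$genes))
em  <- sim$expression[, .(rpkm = mean(rpkm)), by = gene_id]
correlation_by_region(rme, em)
#>    region_class context        rho      p_value     n
#> 1:   downstream      CG  0.2055989 2.427343e-02   120
#> 2:     genebody      CG  0.2241081 1.386783e-02   120
#> 3:     upstream      CG -0.3687568 3.408967e-05   120
```

The signs match the biology the generator encodes: upstream (promoter)
methylation correlates negatively with expression (rho = −0.37,
p = 3.4e−05), gene-body methylation positively (rho = +0.22). Linking the
called DMRs to genes and crossing with DEG direction gives the quadrant
table:

```r
links <- link_dmrs_to_genes(dmrs, sim$genes)
quadrant_table(links, degs)[count > 0]
#>     context region_class expr_dir meth_dir count
#>  1:      CG   downstream       E+       M+     2
#>  2:      CG   downstream       E+       M-     3
#>  ...
#>  8:      CG     upstream       E+       M+     7
#>  9:      CG     upstream       E+       M-     3
```

The whole pipeline can also be driven from a JSON config of file paths
(annotation BED/GTF, per-sample call tables, expression matrix, optional GMT
gene sets) with `run_pipeline("config.json")`, which writes every result
table plus a manifest to an output directory. A thin command-line wrapper is
installed at `system.file("cli/methylink.R", package = "methylink")` with
`simulate` and `run` subcommands.

## Tests and reproduction

The testthat suite (unit tests with exact brute-force oracles, plus
end-to-end acceptance tests) runs with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "methylink", load_package = "installed")'
```

`scripts/acceptance.R` recomputes the headline quantities from scratch
against the installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

For seed 1 this reports, among others: direction-correct DMR sensitivity
1.00 (60 injected DMRs), DEG sensitivity 0.93 (100 injected DEGs), upstream
Spearman rho −0.408 (n = 500 genes), gene-body rho +0.121, DMR false
positive rate 0.064 under a shared-methylome null (9,998 windows), and the
metagene minimum exactly at the TSS bin. Everything is seed-deterministic;
re-running with the same seed reproduces the JSON byte for byte.
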