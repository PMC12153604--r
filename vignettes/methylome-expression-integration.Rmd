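---
title: "Methods: integrating WGBS methylomes with expression"
author: "methylink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating WGBS methylomes with expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylink)
library(data.table)
```

# Scope

`methylink` analyses whole-genome bisulfite sequencing (WGBS) cytosine call
tables together with per-sample gene expression (RPKM) for a two-group design
(a high group `H` and a low group `L`, typically 4 biological replicates
each). It computes region-level methylation, metagene profiles, differential
methylation regions (DMRs), differentially expressed genes (DEGs), and the
statistical association between the two layers. A self-contained synthetic
data generator with known ground truth supports calibration and recovery
testing of every stage.

# Data model

**Methylation calls.** One row per covered cytosine per sample: chromosome,
1-based position, strand, sequence context (`CG`, `CHG`, `CHH`), count of
methylated reads and total reads. Internally all interval arithmetic uses
0-based half-open coordinates; positions are converted on input and output.
Sites with zero total coverage are dropped on read.

**Methylation level.** All levels are *weighted*: the ratio of summed
methylated reads to summed total reads over the sites of a region,
$\sum m_i / \sum t_i$. This weights deeply covered sites more and is robust at
low per-site depth, unlike averaging per-site ratios. Sites below a coverage
floor (default 4 reads) are excluded from region levels and profiles.

**Gene regions.** Each gene contributes three strand-aware regions: upstream
(5' flank), gene body, and downstream (3' flank), with a 3 kb flank on each
side. For minus-strand genes the genomic right flank is the upstream region.
Flanks are clipped at chromosome boundaries and empty regions are dropped.

**Metagene profile.** Each flank is cut into 30 fixed 100-bp bins and the
body into 60 proportional bins, oriented 5'→3'; genes shorter than 60 bp are
excluded so every body bin is non-degenerate. The profile reports the mean
per-site methylation ratio per bin across all genes of a group.

# Differential methylation

DMRs are called per context by a sliding-window scan:

* window 200 bp, step 50 bp;
* reads are pooled across replicates within each group at each site;
* a window is testable when both groups cover at least 4 common sites;
* windows with an absolute pooled level difference below 0.1 are not called;
* the test is a two-sided Fisher exact test on the pooled 2×2 table
  (methylated/unmethylated × H/L) at $\alpha = 0.05$;
* overlapping significant windows of the same direction are merged, and each
  merged span is re-pooled and re-tested as one table.

The Fisher p-value is computed directly from the hypergeometric mass function
(summing all fixed-margin tables whose probability does not exceed that of
the observed table, with a `1 + 1e-7` relative tolerance, matching
`stats::fisher.test`). This is vectorised and fast enough to scan hundreds of
thousands of windows in seconds; unit tests cross-check it against both
`fisher.test` and brute-force enumeration.

**Calibration caveat.** Pooling reads across replicates treats reads as the
unit of replication. When replicates carry true biological variation in site
levels (overdispersion), the pooled Fisher test is anticonservative for
inference about group means — this is a known property of read-pooling DMR
callers, and callers of this pipeline should treat DMR p-values as a ranking
device rather than strict error control. Under a shared-methylome null
(both groups binomially sampled from the *same* realized site levels) the
test is calibrated; `simulate_null_calls()` constructs exactly that null and
the test suite verifies a false positive rate near the nominal 5%.

# Differential expression

Expression is compared by Welch's unequal-variance t-test on
$\log_2(\mathrm{RPKM} + 1)$, with the fold change defined on the same
pseudocounted scale. A gene is a DEG at raw $p < 0.05$. DEGs are further
classified by a threshold rule at RPKM = 1: `special_up`/`special_down` when
every sample of the lower group is below the threshold and every sample of
the higher group above it, otherwise `other_up`/`other_down`. Genes are also
binned into expression classes non ($\le 1$), low ($\le 10$), middle
($\le 100$) and high ($> 100$) RPKM, and into methylation classes (None for
exactly-zero levels, then tertiles Low/Middle/High by rank, remainders
assigned to the lowest class first and ties broken by gene identifier so the
classification is deterministic).

With 4 vs 4 samples a t-test is low-powered; the synthetic recovery tests
inject a log2 fold change of 2 precisely because smaller effects are not
reliably detectable at this design size.

# Integration

* **Region–expression correlation.** Spearman correlation between a region's
  weighted methylation level and mean RPKM across genes, stratified by region
  class and context. Rank correlation is computed as Pearson correlation of
  ranks; for $n \le 9$ tie-free samples the permutation distribution is
  enumerated exactly, otherwise the usual t approximation on
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ is used.
* **DMR–gene links.** A DMR is assigned to every gene whose upstream, body or
  downstream region contains the DMR midpoint (a DMR between two genes can
  link to both).
* **Quadrants.** Links whose gene is a DEG are tabulated into
  E±/M± quadrants per region class, zero-filled over the full grid.
* **Expression change by DMR direction.** All linked genes (not only DEGs)
  contribute their log2 fold change, summarised by median per DMR direction.
* **Enrichment.** Hypergeometric upper-tail test
  (`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`) of a study set against
  gene sets over an explicit background, optionally BH-adjusted.

# Synthetic data generator

`sim_config()` / `simulate_dataset()` produce a complete dataset with truth
tables. Design choices and defaults:

* **Annotation**: genes placed sequentially on one chromosome with at least
  6 kb plus a gap between neighbours, so flanks never overlap; CpG positions
  follow a geometric spacing (mean 30 bp within genes' neighbourhoods).
* **True methylation profile**: piecewise level with flank 0.65, a TSS dip to
  0.25 (linear recovery over ±500 bp), body 0.75, downstream at the body
  level; non-CG contexts sit at a low constant; 10% of genes are fully
  unmethylated (level exactly 0). Per-gene additive shifts
  (`gene_level_sd = 0.15`) in upstream and body levels create the
  between-gene variation that the integration stage correlates with
  expression.
* **Counts**: per-site, per-sample levels are Beta draws around the true
  level with dispersion $\rho = 0.05$; coverage is negative binomial
  (mean 30, size 8); methylated reads are binomial. Zero-coverage
  site-samples are dropped, as in real call tables.
* **Injected DMRs**: 60 windows of width 600 bp with a level shift of 0.4
  in the H group, direction chosen away from the clipping boundary so the
  nominal effect is fully realized.
* **Expression**: log-linear coupling to the true region levels
  ($\log \mu = 2.5 - 4\,m_{up} + 3\,m_{body}$, noise sd 0.4 on the log
  scale), which produces the expected negative upstream and positive body
  correlations; 25% of genes are forced non-expressed; 100 DEGs with
  log2 fold change ±2 are injected among expressed genes.
* **Determinism**: every stage derives its own seed from the master seed by
  fixed offsets, so the same configuration is byte-identical across runs and
  components can be regenerated independently.

The generator is deliberately simple: one chromosome, no SNPs or conversion
failures, no strand asymmetry in coverage, independent sites apart from the
profile, and group differences only where injected. It is meant for
calibration and recovery testing, not for benchmarking against real WGBS
complexity.

# Problem sizes and verification

The shipped acceptance tests run, per seed (five seeds): 500 genes, 4 vs 4
samples, ≈170 k cytosine sites and ≈680 k call rows per group, in roughly ten
seconds per seed. They verify exact closed-form oracles for the statistical
primitives, null calibration of the DMR and DEG tests, ≥90% direction-correct
recovery of injected DMRs and DEGs, the sign and significance of the
upstream/body correlations, and the canonical TSS dip in the metagene
profile. `scripts/acceptance.R` recomputes the same headline quantities from
scratch for any seed and writes them as JSON.
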