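# pausekit

Quantify RNA polymerase II promoter-proximal pausing from
nascent-transcription coverage.

Pol II frequently initiates and then pauses 20–60 nt downstream of the
transcription start site; release of the paused polymerase into
productive elongation is a central regulatory step, read out directly
by GRO-seq-style assays. `pausekit` is for analysts of such data —
stranded coverage tracks, replicate peak calls, a gene annotation —
who want the standard pause-release analysis as tested, reusable
functions rather than one-off scripts.

The central statistic is the **pausing release ratio** per gene,

&nbsp;&nbsp;&nbsp;&nbsp;PRR = (d_body + c) / (d_promoter + c),

where d_promoter and d_body are mean signal densities (signal per bp
per million total library signal) over a promoter window (TSS − 50 to
TSS + 300 by default) and the gene body (TSS + 300 to the TES), and c
is a pseudocount. Comparing conditions gives
log2(PRR_treat / PRR_ctrl) per gene, and genes are classified as
**Group I (paused)** when log2 PRR fold change > 0.585 (fold > 1.5),
**Group II (other)** when |log2 FC| ≤ 0.585, and **Decreased** below
−0.585, after an optional promoter-activity filter.

Around that core the package provides:

* genomic I/O with validation (GTF/BED12 annotations, bedGraph/bigWig
  coverage, narrowPeak/BED6+ peaks with linear or −log10 FDR columns);
* ECDF tables and the two-sample Kolmogorov–Smirnov comparison;
* TSS-anchored and peak-centered metaplot matrices with bootstrap
  confidence bands;
* FDR-filtered consensus peaks across replicates, cross-assay
  intersection, genomic-feature annotation, and cross-assay
  fold-change (Spearman) correlation;
* hypergeometric over-representation analysis with BH correction;
* a synthetic-data generator with known per-gene truth and a
  controllable pause-release effect, so every stage is testable
  end to end;
* a config-driven pipeline (`run_pausing_analysis()`) with provenance
  sidecars, a digest manifest, and byte-identical reruns.

## Worked example

Simulate a pause-release experiment with known truth and recover the
effect:

```r
library(pausekit)

cfg <- generator_config(n_genes = 300, seed = 42)   # 30% of genes released
gen <- generate_genome(cfg)
ctrl  <- simulate_coverage(gen$genes, gen$truth, cfg, "ctrl")
treat <- simulate_coverage(gen$genes, gen$truth, cfg, "treat")

windows <- build_windows(gen$genes)
prr <- prr_table(windows, ctrl, treat, min_activity_quantile = 0)
head(prr[, c("gene_id", "prr_ctrl", "prr_treat", "log2_prr_fc", "group")], 4)
#>     gene_id   prr_ctrl  prr_treat log2_prr_fc         group
#> 1 gene_0001 0.18742198 0.18262222 -0.03742791 GroupII_other
#> 2 gene_0002 0.07140353 0.19255344  1.43119171 GroupI_paused
#> 3 gene_0003 0.14208780 0.15722365  0.14603561 GroupII_other
#> 4 gene_0004 0.14757205 0.05796852 -1.34807793     Decreased

table(prr$group)
#> GroupI_paused GroupII_other     Decreased      Excluded
#>            85           202            13             0

ks_two_sample(prr$prr_treat, prr$prr_ctrl)
#> Two-sample K-S: D = 0.2933, p = 1.232e-11 (n = 300, 300)
```

The PRR of a gene like `gene_0002` roughly triples on treatment
(log2 FC ≈ 1.43 > 0.585), so it lands in Group I: its paused
polymerase was released into the body. The group table recovers the
generative structure (~30% released → 85 Group I genes, ~5% with the
inverse effect → 13 Decreased), and the K-S test confirms the
treatment PRR distribution is shifted toward elongation. The activity
filter is disabled here because every simulated gene is active; on
real data the default excludes the least-active quartile of promoters,
where the ratio is not meaningful.

Downstream, `matrix_at_anchors()`/`meta_profile()` produce the TSS
metaplots for each group, `consensus_peaks()`/`intersect_assays()`
reduce replicate peak calls to consensus regions, and
`hypergeom_ora()` tests the groups against GMT gene sets.
`run_pausing_analysis()` runs all of it from one config; a thin CLI
wrapper lives in `inst/scripts/pausing-pipeline.R`.

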