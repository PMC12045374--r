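---
title: "Quantifying promoter-proximal pausing with pausekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter-proximal pausing with pausekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

RNA polymerase II frequently initiates and then stalls 20–60 nt
downstream of the transcription start site (TSS). Release of this
promoter-proximal paused polymerase into productive elongation is a
major regulatory step, and nascent-transcription assays (GRO-seq and
relatives) read it out directly: a paused gene shows a sharp signal
peak just downstream of the TSS and comparatively little signal over
the gene body, while a released gene shows the opposite.

`pausekit` summarises this with the **pausing release ratio** (PRR) per
gene:

$$\mathrm{PRR} = \frac{d_\mathrm{body} + c}{d_\mathrm{promoter} + c},$$

where \(d_\mathrm{promoter}\) and \(d_\mathrm{body}\) are mean signal
densities (signal per bp per million units of total library signal)
over a promoter window and a gene-body window, and \(c\) is a small
pseudocount. High PRR means polymerase has been released into the
body; low PRR means promoter-proximal accumulation. Comparing two
conditions (for instance a knockout of a pausing factor against its
control) gives the per-gene fold change
\(\log_2(\mathrm{PRR}_\mathrm{treat}/\mathrm{PRR}_\mathrm{ctrl})\),
and genes are classified by that fold change:

* **Group I (paused)** — \(\log_2 \mathrm{PRR_{FC}} > 0.585\)
  (fold change \(> 1.5\)): pausing released most strongly on treatment;
* **Group II (other)** — \(|\log_2 \mathrm{PRR_{FC}}| \le 0.585\);
* **Decreased** — \(\log_2 \mathrm{PRR_{FC}} < -0.585\);
* **Excluded** — genes failing the promoter-activity filter before any
  classification.

Group distributions are compared with empirical cumulative
distribution functions and the two-sample Kolmogorov–Smirnov test;
positional signal is summarised with TSS-anchored and peak-centered
metaplot matrices; regions of interest come from FDR-filtered
consensus peak sets intersected across replicates and assays; and gene
groups are tested for pathway over-representation with the upper-tail
hypergeometric test with Benjamini–Hochberg correction.

## Window geometry and key parameters

The windows are the convention of the nascent-transcription pausing
literature, and every bound is a parameter because reasonable variants
exist:

| parameter | default | meaning |
|---|---|---|
| `promoter_up` | 50 bp | promoter window extends this far upstream of the TSS |
| `promoter_down` | 300 bp | …and this far downstream |
| `body_gap` | 300 bp | gene body starts this far downstream of the TSS |
| `body_extent` | to TES | body runs to the TES (or a fixed length clipped there) |
| `pseudocount` | 0.1 | density added to both PRR terms |
| `log2_threshold` | 0.585 | \(\log_2 1.5\), the Group I/II boundary |
| `min_activity_quantile` | 0.25 | control promoter-density quantile below which genes are Excluded |

Genes too short to leave a non-empty body window are omitted (with
their ids reported), never truncated to zero-width windows. Windows
are strand-aware throughout: a minus-strand gene's windows are the
mirror image of a plus-strand gene's, and stranded quantification uses
sense-strand signal only (engaged polymerase is directional), while
unstranded tracks such as ATAC use the combined signal.

Numerical choices worth knowing:

* Boundary equality \(|\log_2 \mathrm{PRR_{FC}}| = 0.585\) is assigned
  to Group II. The strict inequalities of the classification leave the
  boundary unassigned; it is a measure-zero case but a deterministic
  rule is required.
* With `pseudocount = 0` the raw ratio is returned and can be `Inf` or
  `NaN` for silent windows; the default 0.1 keeps silent promoters
  finite without dominating active ones.
* The fold-change orientation is treatment over control, so that pause
  release on treatment gives positive \(\log_2 \mathrm{PRR_{FC}}\);
  `flip_fc = TRUE` reverses the convention when the opposite contrast
  is wanted.
* The K-S p-value uses the asymptotic two-sided distribution
  (`exact = FALSE`); the intended use is gene-scale samples (hundreds
  to thousands), where the exact small-sample computation is
  irrelevant.
* The activity filter is quantile-based and aimed at real data, where
  a sizeable fraction of annotated genes is silent and a silent
  promoter makes the PRR ratio meaningless. On data where every gene
  is active (including the synthetic genomes below) a quantile filter
  would mechanically discard the configured fraction of perfectly
  measurable genes, so analyses of such data should set
  `min_activity_quantile = 0`.

## Consensus peaks and annotation

Replicate peak sets are combined by per-base occupancy: after dropping
peaks with FDR above `fdr_max` (default 0.05), bases supported by at
least `min_sets` sets (default: all) seed consensus regions, which then
take the union extent of every contributing peak (transitively, so
chained overlaps merge) and inherit the minimum FDR among them. A
reciprocal-overlap rule is available as an alternative linking
criterion. Cross-assay intersection defaults to the strict per-base
intersection — the result can never exceed either parent, which keeps
downstream density windows conservative — with the union extent as an
option.

Peaks are annotated with precedence promoter > exon > intron >
distal-intergenic (a peak touching any promoter window is "promoter"
regardless of other overlaps), with the promoter window defaulting to
TSS ± 2 kb. When no exon models are supplied each gene is treated as a
single exon spanning its body, so genic non-promoter peaks are
reported as exonic; pass an `exons` GRanges for annotations that
distinguish introns.

## Metaplots

`matrix_at_anchors()` builds a genes × bins matrix of library-normalized
signal over a window (default −100 bp to +2 kb around the TSS, 10 bp
bins, giving 210 columns; the window is the display convention of the
field, the bin width a plotting resolution choice). Minus-strand rows
are flipped so column 1 is always 5′-most. Window parts beyond a known
chromosome end are missing values, not zeros — zero-fill would bias
column means downward at edges; partial edge bins average their
in-genome bases. `meta_profile()` adds a bootstrap confidence band
(row resampling, seeded, default B = 1000) because averaged profiles
without uncertainty invite over-reading. `centered_matrix()` does the
same around peak midpoints, unstranded, for accessibility-style data.
Whether to library-normalize is a flag (`normalize`); spike-in style
normalization is up to the caller via `library_total`.

## Over-representation analysis

`hypergeom_ora()` is the standard upper-tail hypergeometric test of a
query gene group against each gene set, BH-adjusted across sets. The
universe defaults (in the pipeline) to the classified gene list — the
genes that actually entered the analysis — rather than the whole
annotation, since the question is whether a pathway is enriched among
Group I genes relative to the genes that could have been in Group I.
No pathway database ships with the package; gene sets are user input
in GMT format.

## The synthetic-data generator

`generator_config()` / `generate_genome()` / `simulate_coverage()` /
`simulate_peaks()` emulate the structure of a pause-release
experiment:

* non-overlapping genes on one chromosome, random strand, lengths
  log-uniform in 2–20 kb, intergenic gaps of 1–3 kb — gene-scale
  realism without chromosome-scale detail;
* per-gene control body rates log-normal (median 0.5 signal/bp,
  log-sd 0.5), promoter rate = body rate × `promoter_enrichment`
  (default 10). Genes destined to respond (`paused_released`, default
  30%) get a further `paused_extra_enrichment` (default 2×): the
  responding genes are the highly paused ones, which is what makes the
  control metaplot contrast between eventual Group I and Group II
  genes realistic;
* the treatment divides the promoter rate and multiplies the body rate
  of released genes by \(\sqrt{\mathrm{release\_fold}}\) (default
  fold 3), then rescales both so each gene's expected total signal is
  exactly conserved. The naive symmetric effect alone does not
  conserve totals (body mass dominates), and the resulting library-size
  shift would masquerade as a distributional change for unaffected
  genes; the rescale isolates the ratio effect from expression change,
  which is the point of the simulation. A small fraction
  (`fraction_gained`, default 5%) receives the inverse effect;
* per-base counts are Poisson (drawn by total-count thinning, which is
  exactly equivalent and fast), sense strand only, over a uniform
  two-strand background (0.01/bp). Optional gamma overdispersion is
  available but off by default — Poisson is the simplest model that
  exercises the estimators;
* replicate peak calls cover each promoter with ±20 bp boundary
  jitter and FDR < 0.01, plus 20% decoy peaks with FDR in [0.05, 1];
* all randomness derives from one root seed via fixed sub-streams, so
  every artifact is reproducible independently.

What the generator does **not** emulate: mappability, GC and
fragment-length structure, enhancer transcription, antisense/divergent
initiation, multi-chromosome genomes, and biological between-replicate
variability beyond boundary jitter. Passing recovery tests on this
data therefore shows the estimators are correct and well-calibrated
under the stated noise model — not that any particular biological
dataset will classify cleanly.

## Problem sizes and verification

The package's checks run at these scales, chosen to give stable
statistics at desk-scale cost: interval/K-S/hypergeometric oracle
comparisons on 1,000 random small instances each (≤ 50 intervals on
≤ 10 kb chromosomes; samples ≤ 40; universes ≤ 12 for exhaustive
enumeration); parameter recovery on a 2,000-gene genome (30% released,
10× enrichment, 3× release) where ≥ 90% of truth-released genes must
classify Group I and ≥ 90% of truth-unchanged genes Group II, with the
treatment-vs-control K-S test rejecting (p < 0.01) on the released
subset and not rejecting (α = 0.05) on the unchanged subset across 20
seeds; null ORA calibration over 10,000 simulated tests with a large
universe (10,000 genes, sets of 100–1,000) so the discrete
hypergeometric p-value is in its near-continuous regime; and full
byte-identity of pipeline reruns. `scripts/acceptance.R` recomputes
the headline quantities from scratch at the same scales.

## The pipeline

`run_pausing_analysis()` wires the stages together from one config
(buildable with `run_config()` or loaded from YAML): consensus →
cross-assay intersection → annotation → windows → densities → PRR →
classification → ECDF/K-S report → group metaplot profiles → ORA.
When peak files are supplied, the gene universe is restricted to genes
whose promoter window overlaps the cross-assay consensus — the
multi-assay gene selection used when several genomics readouts must
agree. Every output is TSV with a provenance sidecar (inputs,
parameters, seed) and the run manifest records md5 digests; a rerun
from the same config is byte-identical. `validate_run_config()`
returns problems as data so configuration errors surface before any
stage runs. A thin command-line wrapper over the same functions ships
in `inst/scripts/pausing-pipeline.R`.

## Known limitations

* The PRR is a windowed summary; it does not locate the pause site,
  and genes with internal TSSs or overlapping transcription units will
  mix signals.
* Exon/intron annotation requires user-supplied exon models; with
  gene-span input the intron class is unused.
* The K-S test treats genes as exchangeable draws; correlated genes
  (shared domains, duplicated loci) violate that silently, as in any
  gene-level distributional test.
* bigWig support is pass-through via rtracklayer; bedGraph is the
  reference text format for exact round-trips.
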