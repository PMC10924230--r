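---
title: "Methods: effect-size DMR calling from RRBS coverage tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effect-size DMR calling from RRBS coverage tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsdmr)
```

# The procedure and its assumptions

`rrbsdmr` operates strictly downstream of bisulfite alignment: its input
is per-sample CpG count tables in the six-column Bismark coverage layout
(chromosome, position, position, percentage, methylated count,
unmethylated count). The counts are authoritative; the percentage column
is only cross-checked on read (a deviation above 0.5 points raises a
warning and the counts win).

The analysis chain makes four assumptions worth stating explicitly:

1. **Joint scoreability is a locus property.** A CpG enters the analysis
   only if it is reported in *every* sample and its coverage exceeds the
   scoreability bound in every sample. Loci missing from any sample are
   excluded *before* the coverage test — a coverage criterion "across all
   samples" is undefined for a locus a sample never reported. One filter
   pass is applied jointly across both groups of a comparison, not per
   group.
2. **Proximity implies coherence.** CpGs within 50 bp are aggregated into
   one region and analysed as a unit. Chaining is transitive (single
   linkage): a dense CpG island chains into one long region even where
   its ends are far more than 50 bp apart. Any non-transitive variant
   would need an arbitrary tie-break for where to cut a chain, which the
   underlying method does not define.
3. **Reads are the unit of evidence.** Region methylation is the
   coverage-weighted pooled percentage: counts are summed over member
   CpGs and group samples, then divided. Every read counts once; a
   deeply covered CpG legitimately influences its region more than a
   marginal one. The unweighted per-CpG mean is available
   (`region_methylation_unweighted()`) for sensitivity analysis; the two
   differ whenever member coverages differ.
4. **The call is a pure effect-size threshold.** A region is called when
   the absolute pooled methylation difference exceeds the threshold — no
   test statistic, no multiple-testing correction. This mirrors
   threshold-based RRBS analyses; its false-call behaviour is therefore
   a property of read depth, which the synthetic null quantifies (below).

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_cov_exclusive` | 8 | reads | scoreability: coverage must be **strictly** greater in every sample (≥ 9). The strict reading is deliberate; an inclusive rule is `min_cov_exclusive = k - 1`. |
| `max_gap` | 50 | bp | chaining distance between consecutive CpG cytosine positions; the bound is inclusive (a gap of exactly 50 merges). |
| `min_cpgs` | 1 | CpGs | minimum region size; singletons are kept because the method defines no minimum. |
| `delta_threshold` | 5 | percentage points | **strictly** exceeded to call: Δ of exactly ±5.0 is `unchanged`. "5%" is 5 points of absolute methylation, not 5% relative change. |
| `tss_window` | 100 | bp | half-width of the near-TSS annotation window. |
| `promoter_window` | 2000 | bp | upstream extent of the promoter band. |
| `bin_width` | 5 | points | delta-histogram bin width; bins are left-closed right-open except the final, closed bin. |

The sign convention is Δ = treatment − control, so "demethylation upon
treatment" is Δ < −5.

## Annotation windows and priority

Peak-style annotation tools classify by first match in a fixed priority
order. We use TSS > promoter > exon > intron > intergenic, with the
near-TSS window `[tss − 100, tss + 100]` and a strand-aware upstream
promoter band `[tss − 2000, tss − 101]` (mirrored on the minus strand).
These window sizes are conventional rather than canonical — annotation
tools differ — so both are arguments. Distances are measured from the
region midpoint `floor((start + end)/2)`; the sign is negative when the
midpoint lies upstream of the TSS in the gene's orientation, and
summaries use the absolute distance in kb. Nearest-TSS ties are broken
toward the lower-coordinate TSS, then the lexicographically smaller gene
id, so queries are fully deterministic.

## Conservation

A DMR is *conserved* when it overlaps (≥ 1 bp, 1-based inclusive) a
same-direction DMR of another comparison. Since no convention fixes which
comparison is the denominator, `conserved_fraction()` reports both
orientations plus a symmetric Jaccard-style ratio (conserved regions in
either set over all regions in both sets). An optional minimum
reciprocal-overlap fraction (default 0) tightens the criterion.

# The synthetic methylome generator

The generator (`sim_config()`, `simulate_methylomes()`,
`simulate_gene_annotation()`) emulates the statistical structure the
analysis relies on:

* **Clustered CpG positions** — inter-CpG gaps are a two-component
  mixture: with probability 0.88 a within-cluster gap (2 + geometric,
  mean 15 bp), otherwise a between-cluster gap (51 + geometric, mean
  3,200 bp). This yields CpG-dense islands separated by long gaps —
  the coverage profile RRBS enrichment produces — at ~50,000 CpGs over
  2 × 10 Mb.
* **Overdispersed coverage** — negative binomial, mean 50, size 5
  (coefficient of variation ≈ 0.5). Zero-coverage draws leave the CpG
  absent from that sample's table, as real coverage files omit uncovered
  CpGs; this exercises the joint-locus intersection.
* **Beta-binomial methylation** — each cluster draws a baseline level
  from Beta(0.7, 0.7) (the bimodal low/high pattern of real methylomes);
  each CpG, per sample, draws its methylation probability from
  Beta(μ·c, (1 − μ)·c) with concentration c = 100 and then binomial
  counts. `meth_precision = Inf` switches to pure binomial for analytic
  checks.
* **Planted DMRs with ground truth** — 200 clusters of 4–12 CpGs get
  their treatment-group mean shifted by ±25 points (half up, half down
  by default), clamped to [0.01, 0.99]. Planted clusters draw baselines
  for which the full shift fits inside the clamp bounds, so the planted
  effect size is exact; if a user-requested shift cannot fit, the
  achieved delta is recorded in the truth table with a warning. Because
  clusters are, by construction, separated by more than 50 bp, each
  planted region maps to exactly one assembled region and recovery is
  well defined without fuzzy matching.
* **One library per condition** (`group_sizes = c(control = 1,
  treatment = 1)`) — matching the motivating design, which contrasts
  individual cell-line libraries rather than replicate groups.

The simulated gene annotation packs non-overlapping 2–50 kb multi-exon
genes (2–8 exons, random strands) with exponential intergenic gaps
rescaled to the available space. The `tss_stratified` placement mode
plants positive deltas within 2 kb of a TSS and negative deltas at least
50 kb from every TSS, giving a scenario with a known distance/context
contrast between directions.

**What the generator does not emulate:** bisulfite conversion failure,
M-bias, SNP contamination, strand-resolved CpG reports, chromosome-scale
covariation of methylation, replicate-level biological variance beyond
the beta-binomial, and fragment-level (MspI digestion) coverage
correlation between neighbouring CpGs. Tests passing on synthetic data
therefore validate the *bookkeeping and statistics* of the pipeline —
filtering, chaining, pooling, thresholding, annotation, overlap — not
robustness to these artefacts.

# What to expect from an effect-size threshold at 50× depth

With one library per condition, the per-region delta estimate carries
read-sampling noise with standard deviation approximately

  100 · sqrt( 2 μ(1 − μ) · (Σᵢcᵢ²/N² · 1/(c+1) + 1/N) )

for a region with per-CpG coverages cᵢ summing to N per group,
methylation level μ, and beta-binomial concentration c. At the default
depth (N ≈ 50 × n_cpgs) this is ~4 points for a typical 6-CpG region —
so recovered planted effects of 25 points are measured with an RMSE of
roughly that size (the acceptance script reports the measured value),
and a few-point effect-size threshold alone cannot separate small true
effects from noise at these depths. The null simulation makes the same
point from the other side: the fraction of regions called with no
planted effect falls as coverage grows, and is small (≲ 5%) only once a
region pools ≥ 1,000 reads per group. This is a property of the method,
faithfully reproduced, not of the implementation.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; BED dialects
  convert at the boundary (BED12 `chromStart + 1`; BED3 export converts
  back). Chromosome names are exact strings ("chr1" ≠ "1"), and ordering
  is lexicographic by chromosome then numeric by position.
* Region ids are `chrom:start-end`, deterministic given the input.
* `delta_histogram()` requires the bin width to divide the range evenly
  and counts a delta of exactly −5 in [−5, 0); +100 lands in the final
  closed bin.
* Zero pooled coverage is an error in `region_methylation()` — it cannot
  occur after scoreability filtering but is guarded for direct calls.
* An empty locus intersection aborts with a hint about genome-build or
  chromosome-naming mismatches, the most common cause in practice.
* Empty direction groups are skipped with a warning in
  `distance_summary()` and get `NA` percentages in
  `context_composition()`.
* Gzip is detected by the `.gz` suffix on read and write.

# Validation scales

The test suite validates each stage against independent oracles:
region chaining against graph connected components (1,000 random
instances of up to 500 positions with gaps uniform in 1–200 bp);
scoreability against a per-locus brute force (500 random matrices);
annotation against an all-genes interval scan (500 random gene/region
layouts); conservation against an all-pairs overlap scan (500 random
call sets); plus end-to-end planted-DMR recovery, a three-seed null
coverage sweep, and the TSS-stratified scenario at the default
~50,000-CpG scale. The full suite runs in about a minute on one CPU.

# Known limitations

* No inferential statistics: regions are called on effect size alone, so
  at low coverage the called set has many sampling-noise calls (see
  above). Tools with beta-binomial tests (methylKit, DSS) answer a
  different question and are out of scope.
* Scoreability across *all* samples discards loci missing or thin in any
  single library; with many samples this is increasingly conservative.
* Annotation supports the five contexts above; UTRs, TTS windows and
  CpG-island tracks are not modelled.
* The conservation statistic is descriptive; no permutation test of
  overlap significance is provided.
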