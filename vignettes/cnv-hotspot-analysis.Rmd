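---
title: "Linking replication-stress CNV hotspots to large active transcription units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking replication-stress CNV hotspots to large active transcription units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvtu)
library(GenomicRanges)
```

## The scientific problem

Mild replication stress (for example low-dose aphidicolin) induces de novo
copy-number variants (CNVs) and common fragile site (CFS) breakage at a
reproducible set of genomic loci. `cnvtu` implements the analysis chain used
to show that these unstable loci are not random: CNVs cluster into hotspots
that coincide with *large, actively transcribed transcription units* (TUs)
— genes whose nascent transcript spans hundreds of kb to megabases — and
these units replicate late, latest of all in their middles, where deletions
concentrate while duplications accumulate on the flanks.

The package covers five analysis stages plus the statistics and a
synthetic-data generator:

1. **CNV regions** — merge de novo CNV calls into regions, stratify into
   singletons, clusters (2–4 CNVs) and hotspots (≥ 5 CNVs).
2. **Permutation engine** — randomized placement of intervals in the
   mappable genome for clustering significance and feature enrichment.
3. **TU caller** — contiguous transcribed spans from strand-specific
   nascent-RNA bin coverage, with an empirically determined RPKM threshold.
4. **Replication timing** — probe projection, interval scoring,
   late-segment classification, and transcription-stratified timing
   distributions.
5. **TU-relative profiles** — percent-coordinate (metagene) transforms of
   CNV placement and min–max-normalized replication timing.

## Region building and classification

CNV calls longer than 2.5 Mb are set aside first (`filter_large_cnvs`), so
chromosome-arm-scale events cannot nominate uninformative hotspots; the
filter is strict (`length > max_size`). Remaining calls merge whenever the
gap between them is at most 750 kb (`merge_to_regions`); a gap of exactly
750 kb merges. Merging ignores CNV type and treatment, because observed
clusters mix deletions, duplications and inducing agents; type stays on the
member calls for the TU-relative profiles. Classification thresholds
(singleton 1 / cluster 2–4 / hotspot ≥ 5) are parameters of
`classify_regions`. Filtering precedes merging, matching the order in which
the procedure is described; the alternative order would only differ when a
>2.5 Mb call bridges two otherwise separate regions.

```{r regions}
cnvs <- cnv_calls("chr1", c(1e6, 1.5e6, 2.1e6, 9e6), c(1.2e6, 1.7e6, 2.3e6, 9.1e6),
                  c("deletion", "deletion", "duplication", "deletion"))
regions <- classify_regions(merge_to_regions(cnvs, max_gap = 750e3))
region_summary(regions, cnvs)
```

## The permutation null

All Monte-Carlo statistics place intervals under one law: a chromosome is
drawn with probability proportional to its mappable bp, then a start is
drawn uniformly among the mappable slots on that chromosome that fit the
interval entirely; placed intervals may overlap each other. A placement
must lie fully in mappable sequence (rejection sampling, capped at 10^4^
redraws). This is the standard "shuffle" null stated explicitly for
reproducibility; per-chromosome placement and non-overlap constraints are
possible variants but are not implemented, since with interval sets
occupying a small fraction of the genome they change results negligibly.

Empirical p-values use the add-one rule,
`p = (1 + #{iterations ≥ actual}) / (n_iter + 1)`, one-sided in the
observed direction by default (`direction = "auto"`); enrichment and
depletion are reported separately, as the analyses distinguish e.g.
enrichment for transcribed and depletion for untranscribed sequence. The
p-value can never be 0, and a fixed seed makes every result bit-identical.

Two calibration subtleties are deliberate design choices:

* For calibration experiments the direction must be *fixed* (e.g.
  `"enriched"`): choosing the direction from the data halves p-values by
  construction and cannot be uniform under the null.
* Clustering statistics (merged-region counts, maximum member counts) are
  discrete; their conservative add-one p-values are never exactly uniform.
  Calibration checks therefore use the exchangeable-rank form
  (`empirical_p(..., tie_break = "randomized")`), which is exactly
  discrete-uniform under the null. Reported scientific p-values always use
  the conservative form.

`clustering_significance` asks how often randomly placed CNVs (lengths
preserved), merged with the same gap rule, produce at least one region with
`k` or more members. Note that this probability depends strongly on CNV
density: on the compact synthetic reference genome (300 CNVs in 171 Mb
mappable) random placements chain frequently and the ≥ 5 probability is
near 1, whereas sparse genome-scale sets (a few hundred CNVs in ~2.9 Gb)
make even one ≥ 5 region rare. The statistic is faithful in both regimes;
interpretation requires the density context.

## TU calling

Coverage is binned (default 1 kb) per strand. The calling threshold is, by
default, determined from the data: a two-component Gaussian mixture is fit
to the log~10~ RPKM of nonzero bins and the posterior-equality crossing
between the component means is returned (`determine_threshold`). Two
numerical choices matter here:

* Low-count bins put discrete atoms (1 read, 2 reads, ...) into the log
  distribution, which defeats a Gaussian fit; integer counts are therefore
  dithered with ±0.5 uniform jitter before logging (under a local RNG, so
  results stay deterministic and the caller's random stream is untouched).
* If the BIC prefers one component, or no crossing exists between the
  means, the method falls back to a genome-wide quantile threshold with a
  warning.

Bins at or above threshold are chained; sub-threshold runs up to
`max_internal_gap` (default 10 kb) are bridged as coverage dropouts; spans
under `min_length` (default 10 kb) are dropped. These defaults resolve TUs
at the smallest gene scale the analysis discusses; all are arguments. TU
RPKM is computed over the whole called span, introns included, which is
appropriate for nascent-RNA signal. Treated and untreated libraries can be
pooled with `merge_coverage` (summing counts and totals) before calling.

## Replication timing

Timing enters either as a segment track (Repli-seq style weighted-average
score, higher = earlier) or as array probes projected to segments by the
nearest-probe midpoint rule (`project_probes`, Repli-chip log~2~ ratios).
Interval scores are bp-weighted means; intervals without coverage yield
`NA`, never a silent zero. Late segments follow the published Repli-chip
convention ratio < −0.8 (strict), or any configurable threshold; external
late-segment BEDs (e.g. a published mid-S4-to-G2 segmentation) can be used
directly wherever segments are accepted, since that segmentation is defined
by its source rather than recomputed here. Timing histograms
(`stratify_timing_by_transcription`, `timing_by_expression`) are
bp-weighted and normalized to 100% per stratum; RPKM strata default to
quartiles because the original intensity boundaries are not published.

## TU-relative (percent-coordinate) profiles

Positions are expressed as percent distance along a TU: TSS = 0%,
TES = 100%, strand-aware, flanks extending below 0% and above 100%
(default flank: one TU length per side, grid step 1%). The transform is
affine and invertible to within 1 bp. CNV spans increment every grid point
they cross, with the CNV's half-open boundaries mapped so that a CNV
covering a TU exactly marks the whole closed interval [0%, 100%]. A CNV
intersecting several aligned TUs contributes to each alignment by default
(`multi_tu = "once"` counts it only at its largest overlap). Relative
timing rescales the track by the min and max *within the TU body*, so 0
marks the latest and 1 the earliest point of each unit; TUs with constant
or absent timing are excluded and counted. Length strata default to
> 500 kb (large) and 50–200 kb (small).

## Statistics

`fisher_exact` is the two-sided Fisher's exact test under the
probability-at-most-observed rule (computed by `stats::fisher.test`, which
implements exactly that convention; the package's tests verify it against
full hypergeometric enumeration for all small tables). `spearman_cor`
computes mid-rank rho with a permutation p-value (≥ 10^4^ permutations,
seeded) rather than the asymptotic approximation. Group differences between
region strata use two-sided Mann–Whitney tests; the original report does
not name its group-difference test, so this is a documented assumption. No
multiple-testing correction is applied anywhere: raw empirical p-values are
reported, matching the source analyses.

## The synthetic-data generator

`synthetic_model()` fixes the reference study conditions; `generate_dataset`
emits every input the pipeline consumes plus a ground-truth manifest. The
model emulates:

* a 3 × 60 Mb genome with ~5% excluded gaps — large enough for megabase
  TUs and multi-Mb merging gaps, small enough to run in seconds;
* 200 TUs: a log-normal length population (median 30 kb, heavy upper tail)
  plus five planted units of 1.0–2.0 Mb; RPKM log-normal with a negative
  rank-correlation to length (knob `rpkm_length_rho = -0.3`), reflecting
  that the largest units are weakly transcribed;
* Poisson bin coverage at depth proportional to RPKM over each TU's strand
  plus uniform background reads;
* a timing field that is early (score 75) over transcribed bp, late (35)
  over untranscribed bp, with a triangular mid-TU delay growing 20 score
  units per Mb of TU length — encoding forks converging from the unit's
  ends — plus Gaussian segment noise (sd 1.5);
* CNVs drawn from a double-fork-failure risk model: a TU of length `L`
  carries weight `(L / N_s)^2` with fork-stall scale `N_s = 300` kb, against
  a uniform background weight per mappable bp; deletion centers are
  truncated-normal at 50% of the TU (sd 15%), duplication centers sit in
  flank lobes at −25% and 125%; CNV lengths are log-normal with median
  186 kb, the scale reported for human de novo CNV sets;
* 300 CNVs (200 deletions, 100 duplications), consistent with deletions
  dominating induced CNV sets.

All randomness flows from one seed through named per-stage substreams, so
a dataset is exactly reproducible and each stage can be varied
independently. `null_dataset` disables the transcription-dependent risk so
every CNV follows the permutation engine's own placement law — the
calibration input.

What the generator does *not* emulate: sequence context (no A/T-rich
flexibility islands or breakpoint microhomology), chromosome-scale
heterogeneity of gene density, isoform structure within TUs, and realistic
CNV-density-to-genome-size ratios (the compact genome makes random CNV
chaining far more likely than in a 3 Gb genome). Passing recovery tests on
this generator therefore demonstrates the correctness and calibration of
the machinery, not genome-scale effect sizes.

## Problem sizes used in the tests

The packaged checks run the calibration on 200 null replicates of a small
two-chromosome model (199 permutation iterations each), hotspot recovery on
20 seeds of the default model, TU recovery on 20 planted units at
signal-to-noise ≥ 5, and exhaustive statistic enumeration for tables up to
N = 12. These sizes give stable pass/fail behavior in a few minutes of
compute; all are ordinary function arguments and scale up directly.

## Known limitations

* Real supplemental call tables and genome masks are required inputs for
  reproducing published genome-scale counts; no mappability mask is built
  in, because the original mask definition is not published.
* The mixture threshold is a stand-in for an empirically chosen
  transcription cutoff; its exact published value is not printed, so TU
  totals on real data depend on this choice.
* Whether the original simulations permitted placed-region overlap or
  per-chromosome placement is not stated in the main text; the engine's
  law is documented above and fixed.
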