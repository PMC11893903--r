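---
title: "Models and design choices in rloopscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in rloopscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopscreen)
library(dplyr)
```

rloopscreen implements the statistics used to read out DNA:RNA hybrid
(R-loop) phenotypes from four very different assay families — plate-based
recombination-reporter screens, colony pinning arrays, dot blots and
strand-specific DRIP genomics, plus fluorescence imaging of repair foci —
and ships a seeded synthetic-data layer that makes every one of those
statistics testable by parameter recovery. This vignette explains the
models, the tunable parameters that matter, and the choices made where the
design was genuinely open.

## The recombination index and screen scoring

A flow-cytometry screen measures, per well, the fraction of cells whose
recombination reporter has reconstituted a fluorescent gene. Plates are a
dominant batch effect, so every well is divided by its plate median
(`plate_normalize()`); after this the plate median of normalized values is
exactly 1 and multiplying any single plate's raw values by a constant
changes nothing downstream (a unit-tested invariance).

Pooled wild-type wells are partitioned into ten comparison groups
(`build_comparison_groups()`). Whether the original ten groups were batch
blocks or random splits is not derivable from the assay description, so
both are supported: a `batch` column reproduces batch membership exactly,
and the default is a seeded random partition into groups whose sizes
differ by at most one. Mutant-to-group assignment is likewise a seeded
draw, so a full re-run is reproducible.

Each measurement is then scored against its group with the percentile-type
*recombination index*: the percentage of the group lying below it, ties at
half weight. Midranks are used because normalized fractions quantize at
low event counts, and a half-weight tie rule keeps the index unbiased
around 50 under exchangeability; the index is invariant under any strictly
monotone transform applied jointly to the value and the group. The index
is a description, not a test: significance comes from a two-sided
Mann–Whitney rank-sum test of the strain's normalized values against the
pooled wild type, and strains are ranked by that p-value. Raw p-values are
reported because downstream cutoff selection (interaction-density methods)
happens outside this package; a Benjamini–Hochberg column is appended for
convenience. A strain is called `hyper` when its median index exceeds 50
at p below the reporting threshold (default 0.05), `hypo` below 50.

The prescreen rule (`prescreen_hits()`) carries a strain forward when its
normalized value exceeds the 95th percentile of the pooled wild type in at
least two of four replicates. The percentile is the type-7 (linear
interpolation) sample quantile; the tests pin it against an independently
coded sorted-rank oracle.

The pinning screen is simpler: 16 array positions pinned onto 3 selective
plates give 48 Bernoulli colony calls per strain. Colony positivity is a
size threshold with the boundary counted positive — the upstream scorer
this mirrors is a presence/size caller whose exact criterion is not
restated, so the threshold is an explicit required argument that is
logged. Strains whose fraction of pre-selection growth falls below a
threshold (default 0.75) are excluded before any testing, mirroring the
exclusion of poor growers to avoid selection bias, and never appear with
p-values. Scoring is a two-sided Fisher exact test of each strain's
positive/negative calls against the pooled wild-type calls; the test suite
verifies `fisher.test` against exhaustive hypergeometric enumeration on
small tables rather than trusting it blindly.

## Dot-blot hybrid levels

Serial dilutions of a reference sample define, per detection channel
(S9.6 for hybrids, dsDNA for loading), a log–log standard curve fitted by
least squares. Linearity is assessed by R²: while it stays below `r2_min`
(default 0.98) and more than three points remain, the highest-amount point
is dropped — membrane saturation happens at the top of the dilution
series. Sample intensities are inverted through the standard; each
dilution point yields an estimate of the sample's concentration relative
to the reference and the geometric mean is taken. The reported level is
the S9.6/dsDNA ratio normalized to the reference, which makes it invariant
to per-sample loading and to membrane-wide exposure changes.

Quartile stratification ranks strains by level, Q1 highest, in four
contiguous blocks differing in size by at most one. Size-balanced blocks
(rather than value thresholds) were chosen because the downstream use is a
rank-based comparison of recombination metrics across quartiles, which
wants equal group sizes. Expression categories use strict thresholds
(|log2 FC| > 0.58, p < 0.05); a transcript exactly at the threshold is
`unaffected`. Differential-expression fitting itself is out of scope — the
classifier consumes a results table from any DE engine.

## Spike-in calibrated DRIP

Strand-specific DRIP coverage is binned at 20 bp. The calibration problem:
IP read counts are only proportional to hybrid occupancy within a sample;
between samples the proportionality constant moves with IP efficiency and
sequencing depth. A fixed-proportion spike-in genome (a hybrid-rich strain
mixed at 95:5 with the experimental cells) anchors the scale. The
occupancy ratio

$$\mathrm{OR} = \frac{(n_\mathrm{spike}/n_\mathrm{total})_\mathrm{input}}
                    {(n_\mathrm{spike}/n_\mathrm{total})_\mathrm{IP}}$$

and the calibrated bin value $c = \text{count} \cdot 10^6 /
n_\mathrm{total,IP} \cdot \mathrm{OR}$ were adopted as the spike-fraction
form of calibrated-ChIP normalization: the exact expression of the
original calibration literature differs at most by a sample-constant
factor, and the form used here has the two properties that matter and that
the tests assert — calibrated values are invariant to uniform depth
rescaling of any sample, and scale linearly with true occupancy (log–log
slope 1, R² > 0.95 on the default simulation).

Per-gene densities are mean calibrated signal per bp over the gene body,
separately per strand, with edge bins weighted by overlap. Mean-per-bp
(not total counts) was chosen so that densities are comparable across gene
lengths. The template strand of a `+` gene is the C strand — the strand
the nascent RNA anneals to — and this mapping is fixed package-wide.
RNase H sensitivity is `1 - density_RNaseH / density_mock`; condition
fold-changes use a pseudocount (default 0.01 reads/bp) so zero/zero maps
to 1.

Metagene matrices display 500 bp of unscaled 20-bp bins on each side of
the TSS and TES and a gene body linearly resampled to a fixed number of
columns; rows run 5′→3′ of the gene and are ranked by template-strand
density. A mirrored minus-strand gene reproduces the reversed plus-strand
computation exactly (a symmetry the tests exercise).

Fork orientation comes from the local slope of an OK-seq
replication-direction profile (OLS over the window). Two open conventions
are parameters rather than assumptions: the slope-sign polarity
(`positive_slope_means_rightward` by default, because public OK-seq
polarity varies between processed datasets) and the ambiguity band
(|slope| < 2·SE → `ambiguous`, avoiding coin-flip calls on flat signal).
Co-directional (CD) means fork direction matches the transcription
direction of the gene; head-on (HO) otherwise.

DRIP-qPCR uses %IP = 100 · input_fraction · E^(ΔCt) with the 5% input
aliquot as anchor and ideal doubling (E = 2) by default, configurable per
amplicon within (1, 2]. Adjusted %IP divides by the synthetic spike-in's
%IP, cancelling global IP-efficiency changes.

## Foci imaging

Nucleus segmentation is deliberately plain: Gaussian blur (σ = 2 px),
global Otsu threshold, connected components, minimum area 50 px. The
upstream macro this mirrors is described only qualitatively, so every
parameter is an argument with a logged default rather than an inferred
constant. Foci are local maxima in the maximum-intensity projection:
a pixel counts when it equals the maximum filter within `min_distance`
(5 px) and rises above its nucleus' median intensity by `prominence`
(0.5) times the image's signal scale (max minus median). Defining
prominence relative to the signal scale makes counts invariant to uniform
intensity rescaling; plateaus of equal maxima are collapsed to one count;
maxima outside every nucleus are discarded. Group comparisons form the
2×2 table of foci-containing versus not (threshold ≥ 1 focus, a
configurable definition) and apply the two-sided Fisher exact test.

## The synthetic-data layer

The generators emit exactly what the scorers consume, plus first-class
truth tables — never reconstructed after the fact — so acceptance is
parameter recovery.

- *Flow wells* are logit-normal: `logit(p) = logit(baseline) + plate
  effect + log(fold) + well noise`. A multiplicative effect on the odds
  keeps fractions in [0, 1] while preserving the plate-median
  normalization story. Defaults: baseline 1%, plate effect SD 0.2, well
  SD 0.25 on the log-odds scale. The wild-type well-to-well spread is not
  a published number; it is a config parameter, and the fold-recovery test
  is phrased on the log-odds scale where the planted effect lives (the
  ratio of raw fractions is compressed below the odds fold at baselines
  where p is no longer small).
- *Pinning grids* are 16 positions × 3 plates of Bernoulli calls at a 2%
  wild-type rate; positive calls get log-normal colony sizes around the
  caller's unit scale.
- *The DRIP experiment* plants template-strand-only hybrid signal at
  `txn_level × hybrid_per_txn` reads/bp per gene over a uniform background
  (0.005 reads/bp, low because genic exclusion of intergenic signal is
  part of the emulated structure), multiplied by `condition_fold` (2) when
  treated and `rnh_residual` (0.1) under RNase H. The spike-in genome's
  per-cell hybrid mass is held constant across samples — that constancy is
  what makes it a calibrant — and IP reads split between genomes in
  proportion to hybrid mass, input reads in proportion to DNA content
  (5% spike). Bin counts are Poisson. Default scale: 200 genes of 1.5 kb
  on a 600 kb chromosome, 2 × 10⁶ reads per sample; these sizes keep the
  default simulation comfortably inside a desktop run while leaving
  per-gene Poisson error far below the planted effects.
- *OK-seq* is piecewise linear with known per-segment slopes (±1 per kb,
  15 points per 15 kb segment) plus Gaussian noise; zero-slope segments
  are planted as `ambiguous`.
- *Foci images* contain disk nuclei (radius 14 px, non-overlapping by
  rejection sampling) and Gaussian point sources (σ 1.2 px, ≥ 7 px apart)
  spread across z slices, with Poisson noise; the focus amplitude is
  `foci_snr` times the background noise SD, and a `noiseless` switch
  returns expectations for exact-recovery tests.

What the generators do *not* emulate, and what passing tests therefore do
not show: read-level sequencing artifacts (mappability, duplicates, GC),
restriction-fragment structure of the immunoprecipitated DNA, cytometer
event-level noise and gating, optical aberrations or uneven illumination,
and any correlation structure between assays beyond what is planted. Tests
certify the statistics under the stated models, not robustness to every
failure mode of real data.

## Numerical conventions and limitations

Coordinates are 0-based half-open everywhere inside the package; bedGraph
is read and written 0-based half-open and GFF3 is converted on read.
Quantiles are type 7; box statistics follow Tukey's definition. Ties in
the recombination index use midranks; ties in quartile assignment break by
stable input order. The Mann–Whitney and Fisher tests are the stock R
implementations (`wilcox.test`, `fisher.test`) — validated in the test
suite against enumeration oracles, not reimplemented.

Known limitations: the comparison-group and mutant-assignment scheme is
one reproducible choice among several the assay description admits;
dot-blot quantification assumes the two channels share the dilution grid;
`gene_density()` assumes within-bin uniformity when weighting edge bins;
the metagene resampler interpolates bin values rather than re-aggregating
base pairs; and the foci counter's relative-prominence rule, while
rescale-invariant, can count one spurious maximum in a focus-free image
whose noise ceiling approaches the planted-signal scale. The pipeline
(`run_pipeline()`) is byte-deterministic for a fixed seed, which the test
suite asserts on the serialized JSON summary.
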