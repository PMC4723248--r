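---
title: "Methods: differential sumoylation, mutant-effect arrays and inclusion quantification"
author: "sumostress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential sumoylation, mutant-effect arrays and inclusion quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`sumostress` implements, as one tested pipeline, the three quantitative
procedures used to characterize rapid protein sumoylation during
hyperosmotic stress in budding yeast and its downstream consequences:

1. **Spectral-count enrichment calling** — which proteins gain SUMO
   conjugation between 0 and 15 minutes of stress, from peptide
   identification tables.
2. **Expression-array analysis** — how sumoylation-deficient mutants of
   the corepressors Tup1 and Cyc8 change the transcriptional response,
   from gene-level two-color log~2~ ratios.
3. **Inclusion quantification** — how often cells form transient
   cytoplasmic inclusions of Cyc8, and how strongly two proteins
   colocalize, from fluorescence images with labeled masks.

Each stage has a synthetic-data generator that emits data with the exact
statistical structure the stage assumes, together with its ground truth,
so every operation is verifiable offline. The generators are first-class,
tested code: their defaults *are* the study conditions, and all
recovery/calibration claims in the test suite refer to those conditions.

# Stage 1: differential sumoylation from spectral counts

## Procedure

Peptide identifications arrive as rows of (protein, peptide, sample,
identification probability, spectral count). The analysis is:

1. **Probability filter.** Keep records with identification probability
   ≥ 0.55 (boundary inclusive). The probability is consumed as given — it
   is the posterior of the upstream search engine, and recomputing it is
   out of scope.
2. **Summing.** Cell (protein, sample) of the count matrix is the sum of
   spectral counts over that protein's surviving peptides in that sample;
   missing cells are 0.
3. **Testing.** Per protein, the fold change is the ratio of total summed
   counts at 15 min to 0 min, and the p value is a two-tailed
   pooled-variance (homoscedastic) t test on the per-replicate summed
   counts. The test runs on per-replicate *summed* counts, not
   peptide-level counts, because the replicate groups are the units being
   compared.
4. **Gate.** A protein is called stress-sumoylated when fold ≥ 3 **and**
   p ≤ 0.01, both boundaries inclusive.

## Edge-case policy

* 0-min total 0, 15-min total positive: fold = +∞, which passes the fold
  gate. A pseudocount is available (`pseudocount` argument) but defaults
  to 0, preserving the "exceeds by ≥ 3-fold" semantics.
* Both totals 0: fold = 1, p = 1 (no evidence of change).
* Both groups constant: p = 1 if the means agree, else 0 (the t statistic
  degenerates to ±∞).

The t statistics are computed row-wise with the classical pooled-variance
formula and `stats::pt`, vectorised over proteins; the test suite checks
the result against `stats::t.test` case by case to 10^-10^ relative
tolerance.

## Count model in the generator

Spectral counts are a semi-quantitative proxy for abundance; the
generator models each protein's per-sample summed count as Poisson with
mean `baseline_mean` (default 20) at 0 min and `baseline_mean × fold` at
15 min for planted proteins. Negative-binomial overdispersion is
available (`dispersion`) but off by default — the simplest model
consistent with count data, and the calibration test deliberately
compares the caller's null rate against an oracle *on the same counts*
rather than against the nominal 0.01, since discreteness shifts the
attained rate. Counts are split uniformly (multinomial) across a
configurable number of peptides, because only the sums matter downstream;
a configurable fraction of records (default 10%) are low-probability
decoys carrying extra counts, so a forgotten probability filter is
detectable as a sum mismatch. Replicates per timepoint default to 3,
configurable.

# Stage 2: expression arrays

## Empirical-null threshold

The spread of log~2~ ratios on a self-self (wt × wt) hybridization is
pure technical noise. The threshold for a real expression change is *k*
standard deviations of that null (default *k* = 3), centered at 0; the
null mean is reported for QC but never subtracted. With the study's null
SD of 0.22 log~2~ units this gives ±0.65–0.66 log~2~, a ≈1.57-fold
change. Two numerical policies matter here: the sample SD uses the *n*−1
denominator, and rounding happens only at display time — the pipeline
never chains a rounded 0.65 into later computations (3 × 0.22 = 0.66;
the 2-decimal fold for that is 1.58, for 0.65 it is 1.57).

## Replicate averaging and mutant-effect ratios

Log~2~ ratios are averaged arithmetically across replicate arrays within
each (strain, timepoint); missing values are excluded pairwise with the
per-cell replicate count recorded. The **mutant-effect ratio** of gene
*g* in mutant *m* at timepoint *t* is

$$\mathrm{effect}(g, m, t) = \overline{\log_2 R}(g, m, t) -
\overline{\log_2 R}(g, \mathrm{wt}, t),$$

a subtraction in log~2~ space that cancels the shared stress response and
isolates what the mutation changes. Significance calling is
boundary-inclusive (|value| ≥ threshold). For unstressed (t = 0)
comparisons the averaged ratios against the common reference are used
directly; stressed timepoints use mutant-effect ratios — the two
presentations of the same thresholding operation.

## Aneuploid-segment detection and masking

A copy-number gain in one biological sample appears as a contiguous run
of genes with uniformly elevated ratios on every array of that sample.
The scan computes each gene's mean ratio across the selected arrays and
reports maximal runs of ≥ `min_run` consecutive genes (genome order, one
chromosome) whose mean exceeds `elevation_cutoff` and which are above 0
on every individual selected array; detected genes are removed from the
masked set returned for all downstream analysis.

Defaults: `min_run = 5`, `elevation_cutoff = 0.4` log~2~. The cutoff is
a deliberate operating point: with three arrays per biological sample and
null SD 0.22, a per-gene mean has SE 0.22/√3 ≈ 0.127, so 0.4 lies ≈3 SE
above the null and ≈3 SE below a +0.8 gain — symmetric power against
both error directions. A cutoff of 3 × null SD (0.66) is appropriate for
single-array thresholding but sits only ≈1 SE below a +0.8 segment mean
and fragments true segments; the zero-false-positive property is still
verified at that stricter cutoff. Even at 0.4, exact recovery of a
+0.8-shift segment is not certain: the every-array-above-zero condition
alone fails with probability ≈1.4 × 10^-4^ per gene-array draw, so a
20-gene segment over 3 arrays is recovered with exact boundaries in
≈97–98% of simulations — the residual is a property of the stated noise
level, not of the scan.

## Telomere proximity

A gene is telomere-proximal when min(start − 1, chromosome length − end)
≤ `max_distance_bp`, with 1-based inclusive coordinates. The cutoff is
not a published constant; the default is 25 kb, configurable, and echoed
in output metadata.

## Clustering

Average-linkage agglomerative clustering with the **uncentered
correlation** similarity Σxy/√(Σx²·Σy²) (cosine similarity — Pearson
without mean-centering, so genes with proportional, same-sign profiles
cluster together even when one is uniformly stronger). Merge heights are
1 − similarity. The average linkage is maintained incrementally with the
weighted Lance–Williams update, which is algebraically exact for
averages; ties break deterministically toward the lowest cluster indices
in creation order. The suite verifies the full merge sequence against an
O(n³) oracle that recomputes every inter-cluster average from the raw
similarity matrix, and against `stats::hclust` on tie-free data. Output
is an `hclust` object plus TreeView-compatible CDT/GTR files.

## Synthetic genome and experiment

The generator's deterministic annotation places evenly spaced 1-kb genes
(2-kb spacing) on three chromosomes in a 45/35/20 split; chromosome ends
coincide with the first/last gene, so telomere-proximity tests have exact
expected answers. Arrays are planted-effect + aneuploid-shift + Gaussian
noise (SD 0.22, the self-self value). The default study plants 16 genes
up ≥ 2-fold in the tup1 mutant at 30 min (15 of them telomere-proximal),
21 in the cyc8 mutant, and a 20-gene +0.8 log~2~ segment in one tup1
biological replicate — the synthetic analogue of the published screen's
gene counts, used as exact-recovery targets. Planted shifts sit 0.8
log~2~ above the 2-fold screen threshold so that replicate noise (SE
0.22·√(2/2) ≈ 0.22 for a duplicate-vs-duplicate effect) does not move
genes across the boundary in either direction at any realistic rate.

# Stage 3: imaging

## Inclusion detection

The published protocol scored "cells with at least one visible
inclusion" by eye; reproducibility requires an operational criterion, so
the package defines one:

1. **Candidates.** Scale-normalized Laplacian-of-Gaussian filtering at
   `n_scales` = 4 scales, σ ∈ [1, 4] px; candidates are strict 3×3 local
   maxima of the across-scale maximum response with positive response.
2. **Domain.** When a nuclear mask is present, detection is restricted to
   the cytoplasm (cell minus nucleus) and the nucleus is flattened to the
   cell's cytoplasmic median *before* filtering. The inclusions being
   scored are cytoplasmic, and an enriched nucleus is itself a bright
   blob whose large-scale LoG response would otherwise mask puncta in the
   perinuclear cytoplasm.
3. **Prominence gate.** A candidate is kept iff its pixel intensity
   exceeds the cell's cytoplasmic median by `min_prominence` (default 4)
   times the cell's MAD. Median, MAD and peak all scale with detector
   gain, making the criterion exactly invariant to multiplicative
   intensity changes — verified as a property test.

With zero noise the gate reduces to "strictly brighter than the flat
cytoplasm", so a spot-free noiseless field yields empty per-cell lists at
any positive prominence. With noise, the per-cell MAD is an estimate from
~10²  pixels, and extreme noise pixels occasionally pass in small cells;
at the default settings per-cell positive/negative calls match planted
truth with sensitivity and specificity ≥ 0.95, which is the detector's
contract.

## Summaries and comparisons

The scoring protocol is the published one: per field, the fraction of
cells with ≥ 1 inclusion; per condition/timepoint, the mean and sample SD
of the per-field fractions (across fields, never pooled cells; default
expectations 6 fields × ≥ 40 cells, with under-protocol inputs computed
but flagged `underpowered`). Conditions are compared with a two-tailed
heteroscedastic (Welch) t test on per-field fractions. Nuclear
enrichment is the per-cell ratio of nuclear to cytoplasmic mean
intensity; zero cytoplasmic mean flags the cell rather than erroring.
Colocalization is the Manders **overlap coefficient**
r = Σ(R·G)/√(ΣR²·ΣG²) over masked pixels of the two channels — the
single overlap coefficient, not the split M1/M2 pair. Line profiles use
bilinear interpolation at evenly spaced points, endpoints inclusive.

## Image generator

Fields are rendered as non-overlapping axis-aligned elliptical cells
(semi-axes 6–9 px by default) with concentric half-size nuclear
ellipses, placed by rejection sampling that fails loudly when the
packing is infeasible. Intensity is cytoplasmic baseline (100), nuclear
baseline × enrichment, Gaussian puncta (amplitude 150, σ 1.6 px) at
cytoplasmic pixels of Bernoulli-chosen positive cells, plus additive
Gaussian noise (SD 10) clipped at 0. Arrays are row-major, origin
top-left, coordinates (row, col) 0-based; masks are integer labels with
0 = background. For two channels, each spot appears in channel 2 with an
overlap probability, and the noise draw can be shared so that overlap
probability 1 yields byte-identical channels. What the generator does
*not* emulate — shading, out-of-focus light, touching cells, vacuoles,
photobleaching — bounds what passing tests say about real micrographs:
they validate the measurement pipeline, not robustness to acquisition
pathology. Segmentation (Otsu threshold, hole filling, watershed on the
distance map, area filter, deterministic relabeling in centroid raster
order) is provided for maskless images; synthetic fields carry
ground-truth masks and use them verbatim.

# Seeding and determinism

Every generator is a pure function of (parameters, seed). Multi-part
simulations derive child seeds from one master seed via
`derive_seeds()` (a seeded `sample.int` draw), so a full pipeline run is
reproducible from a single integer; the pipeline writes every threshold,
seed and output checksum into its JSON manifest, and byte-identical
outputs under a fixed (config, seed) are part of the test contract.

# Problem sizes used by the test suite

Chosen as the smallest sizes at which each claim is a sharp test of its
stated condition: null calibration at 200 × 1000 proteins; planted MS
recovery at 200 runs of the 500-protein study; aneuploidy recovery and
null scans at 100 simulations of 400 genes each; clustering oracle at 50
random 6–10-row matrices; the imaging time course at a 20-seed sweep of
5 fields × 40 cells per timepoint (200 cells per condition, mirroring
the published ≥ 200-cells-per-timepoint protocol).

# Known limitations

* Protein inference is taken as given: shared peptides are attributed to
  whatever `protein_id` the input states.
* The Poisson count model underestimates biological overdispersion; the
  negative-binomial option exists but the calibration tests run the
  default.
* The aneuploidy scan detects elevation only (copy gain); losses would
  need the symmetric rule.
* The imaging stage is strictly 2-D; confocal stacks must arrive as
  projections, and the projection rule is the caller's responsibility.
* The inclusion detector's defaults are operational choices, surfaced in
  the manifest; scoring by eye, as in the original protocol, has no
  unique operational equivalent.
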