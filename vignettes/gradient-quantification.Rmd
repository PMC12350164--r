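---
title: "Quantifying molecular and synaptic gradients: models and methods"
author: "vpngrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying molecular and synaptic gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpngrad)
```

## The scientific problem

Visual projection neurons (VPNs) of the fly optic lobe, such as the
looming-detecting LPLC2 population, convert the retinotopic position of
a visual stimulus into *synapse number*: neurons sampling dorsal visual
space make more synapses onto the escape-driving giant fibre (GF) than
ventral neurons, and receive a complementary gradient of inputs from
downward-motion detectors (T4d/T5d) on their dendrites. The same
population shows graded, within-cell-type expression of recognition
molecules (a dpr13-like dorsal-high gene, a SiaT-like ventral-high gene,
and others), measurable both by single-cell RNA sequencing and by
HCR-FISH puncta counting in expanded light-sheet volumes.

`vpngrad` implements the computational chain that turns raw
measurements into gradient claims:

1. **`synthetic_data`** — seeded generators for all five input kinds
   (expression matrices, image volumes, connectome adjacency tables,
   takeoff records, direction-tuned fluorescence traces), each shipping
   a ground-truth table.
2. **`volumetric_quant`** — the volumetric instance-segmentation
   pipeline: preprocessing,
   Laplacian-of-Gaussian (LoG) nucleus detection, 3-D Voronoi
   partitioning, energy-minimizing threshold segmentation, per-nucleus
   puncta counting and per-brain max-normalization, plus voxel-mask
   overlap.
3. **`expression_gradients`** — QC, TP10K log-normalization, highly
   variable gene (HVG) selection, per-type PCA, covariate association,
   the continuity-versus-discreteness shuffle test, and per-group
   Spearman correlations with bootstrap CIs.
4. **`connectome_gradients`** — per-neuron synapse totals,
   max-normalization, dorsoventral (DV) regression, antiparallel-pair
   checks, and colour-map export.
5. **`physio_behavior`** — looming kinematics, dF/F, directional
   tuning and the directional sensitivity index (DSI), bootstrap CIs,
   smoothed DSI maps, GF peak/area summaries, takeoff-mode
   classification and the elevation-gradient test.

## What the synthetic generators emulate

All generators use a 1-D latent dorsoventral axis on [0, 1]; the y axis
of synthetic volumes is declared dorsoventral (larger y = dorsal).
Defaults were chosen once, for testability at desk scale, and define
the conditions every recovery test runs under:

* **Expression** (`gen_expression`): 600 cells, 30 genes (half with
  log-fold coefficient +2 per unit position, half −2; baseline 20
  counts, NB dispersion 5, variance μ + μ²/dispersion), a lognormal
  per-cell coverage multiplier (sd 0.3 on the log scale), and
  replicate/sex/age metadata drawn independently of the axis. With
  `n_clusters = k` the axis collapses onto k equispaced values,
  emulating discrete subtypes. Real data differ in panel size
  (thousands of genes), in ambient RNA and doublets (not modelled), and
  in covariates that may genuinely correlate with position; passing
  tests show the statistics recover a known gradient under NB noise,
  not that any particular biological dataset is continuous.
* **Volumes** (`gen_volume`): 256 × 256 × 64-voxel stacks (stored
  z, y, x = 64, 256, 256), 30 nuclei of radius ~6 ± 0.8 voxels at
  least two mean radii apart, Gaussian PSF σ = 1.2 voxels, per-nucleus
  lognormal brightness (CV 0.2), per-channel lognormal contrast jitter
  (log-sd 0.1), and Gaussian background (mean 0.05, sd 0.01 of spot
  peak) — the artefact classes a volumetric pipeline must tolerate.
  Per-nucleus puncta counts are Poisson with rates interpolated
  linearly between the ventral and dorsal ends (defaults 2 and 20,
  antiparallel across the two gene channels); puncta are placed
  strictly inside the parent nucleus so the assignment truth is
  unambiguous. No optical modelling beyond the Gaussian PSF.
* **Connectome** (`gen_connectome`): one target neuron, 100 graded
  sources with expected counts slope × position + intercept (defaults
  20 and 2), Poisson or NB noise, optional antiparallel twin sharing
  positions.
* **Behaviour** (`gen_takeoffs`): per elevation, one takeoff per fly;
  short-mode probability rising with elevation (defaults 0.2 to 0.8
  from −30° to 77°); short durations uniform on [2.5, 6.5] ms, long
  durations 7 ms + gamma(3, scale 3).
* **Tuning** (`gen_tuning_traces`): 24 directions (0–345° in 15°
  steps, 0° = upward), peak dF/F to direction θ equal to
  `amplitude × (1 + DSI·cos θ)` so the noiseless recovered DSI equals
  the target exactly; traces sampled at 9 Hz with a Gaussian transient
  peaking 0.75 s after onset, narrow enough that the 0.5-s baseline
  window is uncontaminated.

## The volumetric pipeline

Each channel is preprocessed by quantile-clipped full-scale contrast
stretching (defaults 0.001/0.999, robust to hot pixels), subtraction of
a 3-D Gaussian-blurred copy (local background removal; σ ≈ 3× the
object radius for the nuclear channel, ≈ 4× the PSF for FISH
channels), a second full-scale stretch, and a 3-D median filter
(edge 3 for nuclei; 1, i.e. off, for puncta channels, where the filter
would erode sub-PSF spots). A constant input returns an all-zero
volume with a message rather than an error.

Nucleus centres are local maxima of the scale-normalized negated LoG
response (scale radius/√3 ≈ 3.5 voxels for radius-6 nuclei) above a
threshold, with greedy non-maximum suppression at σ√3 in physical
units. The volume is partitioned into Voronoi cells around the centres
(Euclidean distance scaled by voxel size; ties to the lowest centre
index), and each cell's nucleus is segmented at the threshold t*
minimizing the two-class piecewise-constant energy

E(t) = Σ_{I≥t} (I − μ_in)² + Σ_{I<t} (I − μ_out)²,

whose minimizer coincides with the Otsu-optimal threshold; candidates
are the observed intensities, ties resolved to the smallest, and the
mask is the 6-connected supra-threshold component containing (or
nearest to) the seed. Both the Voronoi partition and the threshold are
tested against exhaustive oracles.

Puncta are LoG maxima on the preprocessed FISH channel. The detection
scale is deliberately *finer* than the PSF (default 0.7 voxels for a
1.2-voxel PSF): at the matched scale, spots closer than about two
voxels merge into a single maximum and counts saturate in high-rate
nuclei; the finer scale resolves near-adjacent spots and raised the
per-nucleus count Spearman against truth from ~0.87–0.92 to
0.92–0.98 across generator seeds. Each punctum is assigned to the
nucleus whose ball-dilated mask contains it (default radius 2, the
"immediate surrounding volume"); a punctum inside two dilated masks
goes to the nearer centre, and unassigned puncta are excluded. Counts
are max-normalized per brain *and per gene* — the per-gene variant is
required for cross-gene comparability on a common 0–1 scale. Raising
the detection threshold can only remove puncta, so counts are monotone
non-increasing in it.

## The continuity shuffle test

Whether within-type heterogeneity is a continuous gradient or discrete
subtypes is decided by two permutation schemes applied to the
gene-standardized expression matrix, recomputing PC1 after every
permutation:

* **Scheme A** permutes each gene independently across all cells and
  compares the observed *coherence* (PC1 variance-explained fraction);
  `p_coherence = Pr(null ≥ observed)`. Small values mean the gradient
  reflects coordinated expression.
* **Scheme B** permutes each gene only within *artificial clusters*
  and compares the *gap* — the largest spacing of the sorted PC1
  scores over their central 96%, standardized by the score sd;
  `p_gap = Pr(null ≤ observed)`. Small values mean the shuffled data
  are gappier than the real data (continuity); large values mean the
  observed gap is already as large as manufactured ones (discreteness).

Two numerical choices matter and were validated on generator data
before being frozen. First, the artificial clusters are k
equal-frequency bins along the observed PC1 (default k = 3), not
k-means: k-means locks onto any true gap, which makes the within-
cluster null exactly exchangeable with genuinely discrete data — the
test then has no power to *accept* discreteness. Quantile bins are
arbitrary by construction; with k = 3 a bin straddles any two-cluster
gap, and shuffling within it creates chimeric cells that fill the gap,
driving p_gap toward 1 for discrete data while within-bin shuffling
still collapses a continuous gradient into separated blobs (p_gap
small). Second, the gap is trimmed (2% per tail) because the edges of
a bounded gradient are sparsely populated and single edge cells
otherwise produce spurious large spacings. At the defaults the test
separated 20/20 continuous from 20/20 two-cluster generator datasets.

## Statistical conventions

* **TP10K**: counts scaled to 10⁴ per cell, then log1p. Cells with
  fewer than 10,000 or more than 50,000 transcripts (or > 10%
  mitochondrial) are removed first; bounds are inclusive on the keep
  side.
* **HVG selection**: variance of normalized values standardized within
  equal-frequency mean bins (default 20, capped so each bin holds at
  least 10 genes); ties broken lexicographically for determinism.
* **PCA**: gene-standardized matrix, 5 PCs by default, each PC's sign
  fixed so its top-|loading| gene loads positively.
* **Covariate checks**: Spearman for continuous, Kruskal–Wallis for
  categorical covariates against PC1; raw p-values (diagnostic, not
  corrected).
* **Bootstrap CIs** (`bootstrap_mean`): 10,000 seeded resamples by
  default. The interval is the *expanded percentile* interval — a
  percentile interval whose quantile levels carry a t-based
  small-sample adjustment — because the plain 2.5/97.5 percentile
  interval covers only ~93.5% at n = 20; the expanded interval
  measured ~95% over 1,000 Gaussian simulations. `expand = FALSE`
  restores the plain interval.
* **Rank tests**: Mann–Whitney U, exact when both groups have ≤ 8
  observations without ties (validated against full enumeration);
  Kruskal–Wallis plus Bonferroni-corrected pairwise follow-ups for
  more than two groups. Mixed-model fits are out of scope; group
  comparisons use bootstrap CIs and rank tests instead.
* **Takeoff modes**: durations ≤ 7 ms are short, > 7 ms long
  (the boundary value is short); the 50-ms outlier exclusion is off by
  default and enabled per experiment. Per-elevation percentages carry
  Wilson 95% CIs; the elevation gradient is tested by chi-squared with
  Bonferroni-corrected pairwise follow-ups.
* **Loom kinematics**: θ(t) = 2·atan(l / (v·τ)) with τ the time to
  contact — the standard convention consistent with the l/v
  parameterization; profiles are truncated and flagged at contact. A
  0.5-cm half-size object at 62.5 cm/s gives l/v = 8 ms. Reported
  angles are full angles; published onset sizes of such scans are
  sometimes printed as half-angles (2·atan(0.5/50) ≈ 1.15° full,
  0.57° half), so comparisons should check the convention.
* **DSI**: (R_up − R_down)/(R_up + R_down) from the 0° and 180° peak
  dF/F, negative peaks floored at 0 so the index stays in [−1, 1]
  (its value with R_down = 0 is exactly 1); undefined (NA) when both
  cardinal peaks are 0. DSI maps are smoothed with a σ = 1 Gaussian
  via normalized convolution, so missing cells are excluded and the
  output range never exceeds the input range.

## Problem sizes and determinism

Recovery checks run at desk scale: one 256 × 256 × 64-voxel volume
with 30 nuclei for segmentation recovery (detection F1 and count
Spearman ≥ 0.9 against truth), 600-cell expression fixtures
(|cor(PC1, latent)| ≥ 0.9), 50 connectome seeds for slope-sign
recovery, 20 + 20 datasets × 1,000 permutations for the shuffle test,
1,000 simulations for bootstrap coverage and 100 for chi-squared
power. Every stochastic operation takes an explicit seed and is
byte-reproducible under it; identical generator specs produce
identical outputs.

## Known limitations

* The volumetric pipeline assumes roughly spherical, well-separated
  nuclei; touching nuclei are split only by the Voronoi geometry.
* Puncta recall is ~85–90% at the default contrast (merging losses at
  high local density); rank-based downstream statistics absorb this,
  absolute counts are underestimates.
* The shuffle test's artificial-cluster count k must not match a true
  cluster count whose boundaries align with the quantile bins; the
  default k = 3 guards the common two-cluster case.
* CZI ingestion, mesh skeletonization, motion correction, doublet
  detection and mixed-model inference are out of scope.
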