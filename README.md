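# vpngrad

Tools for quantifying **molecular and synaptic gradients within a
neuronal cell type**, built around the *Drosophila* looming-escape
circuit. Visual projection neurons such as the LPLC2 population
(~100 looming detectors per hemibrain) translate the retinotopic
position of a stimulus into *synapse number*: dorsal neurons make more
synapses onto the escape-driving giant fibre than ventral neurons, and
the same cells express recognition-molecule transcripts (dpr13-like,
SiaT-like, beat-VI-like) in matching dorsoventral gradients. Testing
such claims requires four quantitative chains, all implemented here for
anyone analysing within-cell-type gradients:

* **Volumetric FISH quantification** — 3-D nucleus instance
  segmentation (Laplacian-of-Gaussian detection, Voronoi partitioning,
  energy-minimizing thresholding: the threshold t\* minimizes
  E(t) = Σ<sub>I≥t</sub>(I−μ<sub>in</sub>)² + Σ<sub>I<t</sub>(I−μ<sub>out</sub>)²)
  and per-nucleus puncta counting, max-normalized per brain and gene.
* **Expression-gradient statistics** — QC (10,000–50,000 transcripts
  per cell, ≤10% mitochondrial), TP10K log-normalization, highly
  variable gene selection, per-type PCA, covariate association, a
  permutation test of gradient continuity versus discrete subtypes,
  and per-group Spearman r<sub>s</sub> with bootstrap CIs so
  scRNA-seq and FISH are compared on one footing.
* **Connectome gradients** — per-neuron synapse totals with a named
  partner, max-normalization, OLS regression of synapse count on the
  dorsoventral axis with 95% CIs, and antiparallel-gradient checks.
* **Physiology & behaviour** — looming kinematics
  θ(t) = 2·atan(l/(v·τ)), ΔF/F, the directional sensitivity index
  DSI = (R<sub>up</sub> − R<sub>down</sub>)/(R<sub>up</sub> + R<sub>down</sub>),
  seeded bootstrap CIs, σ = 1 Gaussian-smoothed DSI maps, giant-fibre
  peak/area summaries, short-mode takeoff classification (≤ 7 ms) and
  the chi-squared elevation-gradient test.

A fifth module generates **synthetic data with known ground truth** for
all five input kinds (expression matrices, image volumes, adjacency
tables, takeoff records, tuning traces), so the whole pipeline is
testable end to end without external data.

## Worked example

```r
library(vpngrad)

## a 600-cell population with 30 genes graded along a latent DV axis
sim    <- gen_expression(gradient_population_spec(seed = 42))
normed <- normalize_log(sim$counts)
g      <- pca_gradient(normed[, select_hvg(normed)], k = 5)
cor(g$pc_scores, sim$truth$position)[1]
st <- continuity_shuffle_test(normed, n_perm = 1000, seed = 42)

## a connectome with a known synaptic gradient (20 synapses per unit DV)
con <- gen_connectome(synthetic_connectome_spec(slope = 20, intercept = 2, seed = 42))
fit <- dv_regression(total_synapses(con$adjacency, "typeA"), con$positions)

## stimulus kinematics and directional tuning
lp  <- loom_profile(seq(0, 0.5, 0.01), l = 0.5, v = 62.5, start_distance = 50)
tun <- gen_tuning_traces(synthetic_tuning_spec(dsi_by_position = c(0.8, 0.1), seed = 42))
directional_tuning(tun[[1]]$traces)$dsi
```

Output:

```
PC1 variance explained: 0.505
cor(PC1, latent dorsoventral position): -0.984
continuity test: p_coherence = 0.000999 , p_gap = 0.000999
synapse gradient: slope = 20.6 [18.4, 22.9], R^2 = 0.78
loom velocity l/v: 8 ms
pos16 (dorsal): DSI = 0.796 (truth 0.8)
pos40 (ventral): DSI = 0.112 (truth 0.1)
```

Reading: PC1 of the standardized expression matrix captures half the
variance and tracks the latent dorsoventral position almost perfectly
(the sign of a PC is arbitrary; the package orients it by the
top-loading gene). Both shuffle p-values are small: permuting genes
across all cells destroys the axis (the gradient is coordinated), and
permuting within arbitrary clusters manufactures gaps larger than any
observed (the data are continuous, not discrete subtypes). The
regression recovers the generated slope of 20 synapses per unit
position inside its 95% CI, the printed looming stimulus (0.5 cm
half-size approaching at 62.5 cm/s) has loom velocity l/v = 8 ms, and
the tuning pipeline returns the generated DSI to within noise.

For image volumes, `gen_volume()` + `quantify_volume()` run the full
segmentation/counting chain; `inst/scripts/vpn-quantify.R` wraps it
for shell use on TIFF stacks written by `write_volume()`.

## Documentation

Every exported function carries roxygen documentation; the methods
vignette (`vignettes/gradient-quantification.Rmd`) describes the
models, parameter choices, numerical conventions and known
limitations.
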