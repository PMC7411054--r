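---
title: "Phenomic profiling of compound screens: models and methods"
author: "phenoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomic profiling of compound screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

High-content imaging screens treat cells with compounds across plates,
batches and concentrations, extract hundreds of morphological features per
cell, and ask whether the induced phenotypes are informative about each
compound's mechanism of action (MoA). `phenoprofiler` implements the full
analysis path from per-cell feature tables to per-MoA distinguishability
scores:

1. **Aggregation** — live cells are summarised per well by the mean and
   median of each raw feature plus the cell count, giving a descriptor
   vector of length $2p + 1$ for $p$ raw features.
2. **Normalization** — every descriptor is z-scored against the DMSO
   vehicle wells: plate-wise control mean subtraction, then division by the
   batch-wise standard deviation of the (plate-centered) control wells.
3. **Signature selection** — a modified minimum-redundancy
   maximum-relevance (mRMR) ranking with a replicate-discrimination AUC
   stopping rule defines the cell line's *imaging signature*.
4. **Active calling** — a treatment (compound x concentration) is
   phenotypically active when its replicates deviate from vehicle
   (Euclidean criterion) *and* agree with each other (reproducibility
   criterion), both thresholds taken from empirical 95th-percentile nulls.
5. **MoA evaluation** — nearest-reference AUC-ROC: each active treatment
   queries all other active compounds ranked by signature correlation;
   per-MoA aggregates get permutation p-values and Benjamini–Hochberg FDR
   control.

A synthetic screen generator with known ground truth makes every stage
testable end to end without any external data.

# The synthetic screen generator

`screen_config()` + `generate_library()` + `generate_plate_maps()` +
`simulate_cells()` emulate the screening design the analysis targets:
384-well plates with 28 DMSO control wells and up to 280 sample wells, two
technical replicates in each of two batches (four replicate wells per
treatment), and concentrations of 0.3, 1, 3 and 9 uM.

The generative model for a live cell's feature value is additive:

$$x = \beta_{plate} + \beta_{batch} + \beta_{well} + \delta_{treatment} + \varepsilon_{cell}$$

with independent Gaussian nuisances at plate, batch and well level and
per-cell noise. The treatment effect is

$$\delta = d \cdot s \cdot \sigma_w \cdot m_c \cdot \frac{c^h}{c^h + EC_{50,c}^h}$$

where $d$ is the effect direction (entries $\pm 1$ on a random subset of
informative features, shared by all compounds of a coherent MoA and drawn
per compound otherwise), $s$ is `effect_size_active`, $m_c$ a lognormal
per-compound magnitude jitter, and the last factor a saturating Hill
potency curve with a per-compound lognormal $EC_{50}$. Because
$\sigma_w = \sqrt{\sigma_{well}^2 + \sigma_{cell}^2 / \bar n_{cells}}$ is
the control well-level SD implied by the nuisance model, `effect_size_active
= 3` plants z-scores of about 3 on affected descriptors after
normalization — effect sizes read directly on the z-score scale.

A note on the well-level nuisance: the per-well offset
$\beta_{well}$ is essential. Without it, averaging hundreds of cells
shrinks the control well-to-well SD to
$\sigma_{cell}/\sqrt{\bar n_{cells}}$ and z-scores degenerate; real
screens always carry well-level variation (seeding density, edge effects,
dispensing). Its SD, like the cell-count distribution
(negative-binomial, mean 400, dispersion 10), is a modelling stand-in
exposed in the configuration — the screening literature does not pin these
distributions down.

Other generator properties:

* **Redundant features** are a linear transform of an informative parent
  plus small noise ($|r| \gtrsim 0.9$), in blocks, so the redundancy
  penalty of mRMR has real structure to find. **Noise features** carry
  nuisance variation but no treatment effect.
* **Multi-MoA compounds** (poly-pharmacology) carry exactly two
  descriptors; the default `frac_multi_moa = 0.18` mirrors a reference
  library in which 82% of compounds are single-MoA.
* **Dead and mis-segmented cells** are drawn with shifted/inflated
  distributions and labelled; the pipeline only consumes the labels
  (training the upstream QC classifier is out of scope).
* **Channels**: each raw feature is tagged BFP/GFP/RFP round-robin, the
  cell-count descriptor is tagged BFP (counting derives from the
  segmentation marker), enabling channel-subset re-selection analyses.
* **Seeding**: one master seed; each stage and each plate derives a child
  seed deterministically, so identical configurations are bit-reproducible
  and simulating a subset of plates reproduces exactly the same wells.

What the generator does *not* emulate: optics and illumination artifacts,
spatial plate gradients, cell-cycle or density-dependent feature
covariance, classifier label errors beyond a fixed rate, and realistic
feature distributions (everything is Gaussian at the cell level).
Passing tests therefore demonstrate the statistical machinery — thresholds
calibrated as constructed, oracles matched, planted structure recovered —
not robustness to every artifact of real microscopy data.

# Numerical and design choices

Several points are stated loosely in the methods literature; the package
fixes them as follows (each is a documented contract, most are unit-tested):

* **Batch SD on centered controls.** The normalization divides by the
  batch-wise sample SD ($n-1$ denominator) of *plate-mean-subtracted*
  control values. Subtract-then-pool makes the z-score a proper
  standardization; the alternative (raw-value SD) would mix plate offsets
  into the scale.
* **Quantile convention.** All empirical thresholds (tau, rho_null,
  winsorization limits) use linear interpolation between order statistics
  (R's type 7) — a bit-exact contract.
* **Winsorization, not row removal.** The 1%/99% trimming of each
  descriptor clips values rather than dropping wells, preserving treatment
  class sizes for the F-statistic.
* **Redundancy is absolute Pearson correlation.** An anti-correlated copy
  of a selected feature carries no extra information, so redundancy is
  $\max_g |r(f, g)|$ over selected $g$; the trade-off score is
  $\mathrm{relevance} \times (1 - \mathrm{redundancy})$, ties broken
  toward the lower feature index.
* **The one-SD stopping rule** uses the SD at the size achieving the
  maximal mean replicate-AUC. Sizes below 3 are not evaluated: with two
  features every pair correlation is exactly $\pm 1$ and the AUC becomes an
  artifact of floating-point tie breaking.
* **Replicate vs non-replicate pairs.** Replicates share compound *and*
  concentration; non-replicates differ in compound *or* concentration for
  the stopping rule, but the reproducibility null uses different-compound
  pairs only, mirroring the active-calling definition. The null caps at
  2 x 10^6 pairs (seeded uniform subsample above that; exact enumeration
  below).
* **Cell-count floor.** Wells with fewer than 100 live cells are excluded
  before active calling; the strictly-greater-than-50% replicate rule then
  applies to the reduced denominator (2 of 3 wells suffice when one well
  was lost).
* **Permutation unit.** A compound's full annotation set moves as a block
  among the active compounds of a cell line, preserving the multi-MoA
  structure and the MoA size spectrum. Empirical p-values use the +1
  correction, $(1 + \#\{null \ge obs\}) / (1 + n_{perm})$, and BH runs
  jointly over all tested (MoA, cell line) pairs.
* **Mixture threshold.** The expression-calling threshold is the 95th
  percentile of the lower-*mean* component ("first mode" read as lower
  mean, not lower weight) of a two-component Gaussian mixture, fitted per
  replicate by EM (mclust, unequal variances) from a deterministic
  quantile-spaced initialization subset, with an equal-variance retry
  before erroring. Calling is at probe-set level: a gene is expressed only
  if all probe sets exceed the threshold in all replicates.
* **Degenerate inputs.** Wells without live cells propagate missing
  descriptors (never imputed); constant descriptors (zero batch control
  SD) are dropped with a warning; zero-variance signatures are excluded
  from correlation rankings with a warning; treatments reduced to a single
  well cannot demonstrate reproducibility and are called inactive.

# Aggregation optimism and what the permutation null looks like

The MoA aggregate takes, per compound, the *maximum* query AUC over its
concentrations, then the *median* across member compounds. This choice is
deliberately forgiving to compounds that resemble their MoA at only some
concentrations — and it is optimistic by construction. One measurable
consequence, which the test suite and the acceptance script both compute:
the mean of the *aggregated* AUC under annotation permutation sits near
0.55 rather than 0.50, because a maximum over a handful of noisy,
correlated per-concentration AUCs has positive bias, and the same bias
fattens the upper tail of aggregated AUCs for phenotypically incoherent
MoAs. The *query-level* permuted AUC is unbiased (mean 0.5, verified in
the unit tests). The permutation p-values are computed against the
aggregated null and therefore account for this bias automatically — which
is exactly why significance is assessed by permutation rather than against
a nominal 0.5.

# Problem sizes used by the tests

The test suite and acceptance script run on scaled-down screens chosen to
exercise every code path at desk scale: the recovery screen uses 60
compounds, 8 MoAs of size 5 (4 coherent at 3 SD, 4 with per-compound
random directions), 4 concentrations, 4 replicate wells, ~200 raw features
(401 descriptors), ~400 cells per well and 1,000 permutations; unit tests
use smaller instances where brute-force oracles (exhaustive pair counting,
greedy re-evaluation, all-pairs Mann–Whitney, hypergeometric tails) are
exact. Full-library defaults (1,008 compounds, 218 MoAs, ~500 features)
are used only where cheap (library composition).

# Known limitations

* One simulated reporter cell line per run; multi-cell-line studies are
  supported by running several configurations and row-binding MoA results
  (as `greedy_cell_line_ranking()` expects), not by a joint simulation.
* The reproducibility null pools all different-compound pairs regardless
  of concentration; restricting to same-concentration pairs is a plausible
  alternative the package does not implement.
* Expression and fitness calling operate on user-supplied matrices; array
  preprocessing (RMA) and CRISPR screen processing are out of scope.
* The signature size chosen on synthetic screens (~100 of 401 descriptors)
  is larger relative to the candidate pool than typical real-screen
  signatures, because the synthetic replicate-AUC curve keeps creeping
  upward with extra mildly-informative features; the one-SD rule is applied
  as specified either way.
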