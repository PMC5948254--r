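---
title: "Seed-based structural covariance networks: models and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based structural covariance networks: models and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnvbm)
```

## The scientific problem

Structural covariance network (SCN) analysis asks which brain regions'
gray-matter (GM) volumes rise and fall *together across subjects*. Given
spatially normalized, modulated GM density images, a small spherical seed
region is chosen at a canonical MNI coordinate, its GM volume is extracted
per subject, and every voxel in the brain is regressed on that seed volume.
Voxels whose density tracks the seed across the cohort form the seed's
covariance network. When subjects carry different variants of a functional
polymorphism — here, a COMT Val158Met-style grouping into Met-carriers
(Met/Met and Val/Met pooled) versus Val homozygotes — the scientific
question becomes whether the *slope* of that seed-to-voxel coupling differs
between genotype groups, and whether seed or cluster volumes predict
cognitive and neuropsychiatric scores.

The package implements this analysis end to end for ten seeds: a six-seed
striatal parcellation (inferior/superior ventral striatum, dorsal caudate,
ventral rostral / dorsal caudal / dorsal rostral putamen) and four
triple-network seeds (entorhinal and posterior cingulate cortex for the
default-mode network, frontoinsular cortex for the salience network,
dorsolateral prefrontal cortex for executive control). Because patient MRI
and genotype data of the motivating study design are not publicly
deposited, the package ships a cohort simulator that plants exactly the
covariance structure the analysis assumes, so every stage can be validated
against known ground truth.

## Statistical models

### Per-group SCN maps

For one genotype group and one seed $s$, with $x_i$ the seed-sphere GM
volume (mL) of subject $i$ and $y_{iv}$ the GM density at voxel $v$:

$$y_{iv} = \beta_{0v} + \beta_{1v}\, x_i + \varepsilon_{iv}, \qquad
  \varepsilon_{iv} \sim N(0, \sigma_v^2),$$

fitted by ordinary least squares independently at every voxel (vectorized,
but numerically identical to per-voxel fits). The SCN contrast is the
one-sided positive $T = \hat\beta_{1v}/\mathrm{SE}$ with $n - p$ degrees of
freedom, because a covariance network is defined by *positive* coupling to
the seed. The voxel-wise group-difference map instead uses a two-sided
contrast on a group indicator.

### Genotype interaction maps

Covariance-strength differences between groups are mapped with the pooled
interaction model (group $g_i$ coded Val = 0, Met = 1):

$$y_{iv} = b_0 + b_1 x_i + b_2 g_i + b_3\, x_i g_i + \varepsilon_{iv}.$$

$b_3 > 0$ exactly when the seed-voxel slope is larger in Met-carriers; the
default report direction is the one-sided Met > Val contrast on $b_3$,
though both directions are computable. Because the group coding saturates
the model, $\hat b_1$ and $\hat b_1 + \hat b_3$ reproduce the separately
fitted per-group slopes identically (this algebraic identity is a unit
test). The pooled formulation assumes equal residual variance across groups
— the standard interaction-contrast idiom in voxel-based morphometry — and
that assumption is a documented limitation; a Welch-style slope contrast is
not provided.

### Thresholding

Voxel-level p-values within the analysis mask are corrected with the
Benjamini–Hochberg step-up rule (via `stats::p.adjust`), at $q = 0.01$ for
SCN and interaction maps and $q = 0.05$ for the group comparison. Surviving
voxels are grouped into connected components and components smaller than
100 voxels are discarded. The phrase "p < 0.01 FDR-corrected with cluster
size > 100 voxels" is ambiguous about order; this package always applies
voxel-level FDR first and the extent filter second, and records both
thresholds in the run manifest. Components of size exactly
`min_cluster_voxels` are kept (the filter discards strictly smaller ones).
Cluster connectivity defaults to the 18-neighborhood (face + edge), with 6
and 26 selectable. Each cluster's peak is its maximal-T member voxel, ties
broken deterministically by the smallest linear voxel index.

### Scalar statistics

Demographics use the two-sided pooled-variance Student t test for
continuous variables and the Pearson chi-square without continuity
correction for categorical ones (Welch and Yates variants are options).
Genotype counts are checked against Hardy–Weinberg equilibrium with the
1-df Pearson chi-square at the estimated allele frequency. ROI-to-behavior
tables report the Pearson correlation per group × ROI × score with
two-sided p-values, flagged at 0.05 (`*`) and 0.01 (`**`) on raw p-values —
matching how such tables are conventionally footnoted — with optional BH
adjustment of the flags.

## The cohort simulator

`simulation_config()` defaults encode the study conditions the package
emulates:

* **Group sizes** 91 Met-carriers vs 101 Val homozygotes, with genotypes
  drawn conditionally on group (P(MM | Met) = $p^2/(p^2 + 2pq)$) at a Met
  allele frequency of $111/384 \approx 0.289$, the frequency implied by
  genotype counts 20 MM / 71 MV / 101 VV. The unconditional
  Hardy–Weinberg sampler is exported separately as `sample_genotypes()`.
* **Geometry** 40 × 48 × 40 voxels at 4 mm isotropic spacing, affine
  centering MNI (0,0,0) on a voxel center. All ten seeds fall inside this
  field of view; full 1-mm MNI grids would be needlessly slow for a
  simulation whose purpose is validation.
* **Anatomy** a smooth "brain" ellipsoid of density 0.8 inscribed with a
  4-voxel empty margin (so zero-padded smoothing conserves mass), 8-mm FWHM
  Gaussian smoothing of baseline and blob profiles, and i.i.d. Gaussian
  voxel noise (default SD 0.05 density units) smoothed with the same kernel
  and rescaled to preserve its marginal variance. Noise covers the whole
  grid — real smoothed images have noise outside the brain too, and
  noise-free background voxels would otherwise carry infinitesimal
  smoothing tails that masquerade as perfect covariance.
* **Planted networks.** Each `network_template()` draws one latent network
  score $s_{it} \sim N(0, 1)$ per subject. The seed sphere gains
  `seed_gain` (0.25) density units per latent SD, so the extracted seed
  volume is a noisy linear readout of $s_{it}$ with exact noiseless gain
  $k_t$ (mL per latent unit, recorded in the ground-truth sidecar). Remote
  target blobs gain `slope_group` × $k_t$ × $s_{it}$ × profile, with the
  smoothed blob profile renormalized to peak 1 — so the voxel-wise
  regression of a blob-center voxel on the extracted seed volume recovers
  `slope_group` *directly*, and the interaction slope recovers
  `slope_met - slope_val`. Defaults plant two striatal networks (dorsal
  caudal and dorsal rostral putamen seeds) with slopes 2 (Met) vs 1 (Val).
* **Behavior** scores are linear readouts of extracted seed volumes plus
  Gaussian noise (default: an MMSE-like score on the dorsal caudal putamen
  seed, an attention score on the dorsal rostral putamen seed), continuous
  and unclipped so the linear ground truth stays exact.

Everything derives from `rng_seed`; regenerating with the same seed is
byte-identical.

### What the simulator does not emulate

Real modulated GM maps have anatomy-dependent density, spatially varying
noise, registration error, partial-volume effects, age/atrophy gradients
and multi-network overlap. Passing the validation suite therefore
demonstrates that the *statistical machinery* is correct and calibrated
under its own assumptions — not that any particular real-data finding
would replicate.

## Numerical choices

* Images are float32 on disk (NIfTI convention) and float64 in memory.
* Smoothing is separable zero-padded convolution with a sampled Gaussian
  kernel truncated at 4σ per axis; anisotropic voxels get per-axis
  σ = FWHM/(voxel size × 2√(2 ln 2)).
* Sphere membership is by voxel-center distance, boundary closed; ROI
  volumes are Σ density × voxel volume, in mL (voxel volume from the
  affine determinant). Partial-volume weighting is out of scope.
* A voxel whose regression residual is zero to double precision
  (RSS ≤ 10⁻²⁰ × Σy²) gets the sentinel T = sign(β)·∞ (T = 0 for an exactly
  constant voxel) and is counted in `n_zero_residual`.
* The analysis mask keeps voxels with strictly positive mean density ≥ 0.1
  (configurable); published pipelines rarely state their implicit mask, so
  the rule is explicit and recorded in the manifest. FDR is computed within
  the mask only, and the seed's own sphere is excluded from cluster
  reporting (self-covariance is trivial).
* Whether images should be masked or scaled by total intracranial volume
  before regression is left off by default; nuisance covariates (age, sex,
  total GM, …) can be added via `analysis_config(nuisance = ...)` but the
  default model has none.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
closed-form simple regression and per-voxel `lm()` fits for the GLM engine
(10³-voxel instances, 10⁻⁸ relative agreement), an exhaustive 2¹⁰
enumeration against the textbook BH step-up rule, triple-loop distance
scans for sphere masks and breadth-first flood fill for connected
components (1000 randomized instances each), and the generator's own
sidecar ground truth for recovery checks. Calibration checks use 200 null
cohorts (30 + 30 subjects, 20³ grids, no planted covariance): the mean
voxel-level false-discovery proportion at q = 0.01 must not exceed
q + 2 Monte-Carlo SE. Parameter recovery uses 50 replicates at the default
study conditions with planted slopes (2, 1) and noise SD 0.02 — the
recovery fixture pins noise at 0.2 × the planted blob-center signal
(~0.1 density units per latent SD), a regime where localization power,
rather than extent-threshold chance, is being measured; the interaction
slope at the blob center must land within 3 SE of 1.0 and the top cluster
peak within one blob radius of a planted center in ≥ 90% of replicates.
These sizes keep the whole suite within a desktop-scale run while leaving
the statistical margins interpretable.

## A worked example

```{r example, eval = FALSE}
library(scnvbm)

# simulate the default two-network cohort (91 Met / 101 Val)
cht <- generate_cohort(simulation_config(rng_seed = 7))

# one seed's covariance network in the Met-carrier group
scn <- build_scn(cohort_group(cht, "Met"), "dorsal_caudal_putamen")
scn$clusters[, 1:6]

# where does covariance strength differ between genotypes?
ia <- fit_interaction(cht, "dorsal_caudal_putamen")
ia$clusters[, 1:6]

# seed volumes against behavior, by group
sv <- extract_volumes(cht, seed_table())
head(correlate_volumes_scores(sv, cht$phenotypes))

# or run everything (group VBM, 10 seeds x 2 groups, interactions,
# peak spheres, correlation tables, demographics, manifest)
run_pipeline(cht, analysis_config(), "results/")
```

## Known limitations

* The pooled interaction model shares one residual variance across groups.
* Correlation-table flags are unadjusted by default (as in conventional
  table footnotes); BH adjustment is an option, not the default.
* No atlas labeling of clusters and no render-quality figures; cluster
  tables report MNI peak coordinates, extents and peak T only.
* The simulator's networks are mutually independent single-latent
  constructions; cross-network correlation is not planted.
* Voxel-level BH-FDR is the implemented reading of "p < 0.01,
  FDR-corrected"; peak-FDR variants used by some SPM versions are not.
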