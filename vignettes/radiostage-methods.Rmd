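---
title: "Radiotranscriptomic staging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiotranscriptomic staging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiostage)
```

## The problem

Distinguishing organ-confined (T2c) from locally advanced (T3b) prostate
cancer is a staging decision with direct therapeutic consequences, and one
that clinical TNM staging gets wrong in a substantial fraction of cases.
`radiostage` implements a radiotranscriptomic analysis of this boundary: it
extracts texture and wavelet features from B-mode and contrast-enhanced
ultrasound (CEUS) images of the tumor region of interest, parameterizes
microvascular perfusion from CEUS refill kinetics, identifies
stage-specific differentially expressed genes and miRNAs, correlates the
two views, evaluates staging classifiers over four feature sets, and
assembles a miRNA-target regulatory network of stage progression.

Because the patient cohorts such analyses are built on are private, the
package ships a first-class synthetic-study generator that reproduces the
statistical structure every stage assumes, making the entire pipeline
testable end to end.

## The synthetic study

`study_config()` fixes the study conditions. The default cohort is 22
healthy controls, 35 T2c and 13 T3b patients, mirroring the motivating
cohort, and clinical covariates are drawn from truncated normals whose
tumor-stage moments match that cohort's published summary table (e.g. T2c
age 70.11 ± 7.90 years; T3b TRUS volume 49.50 ± 19.86 mL). Gleason
categories use the published per-stage counts. Healthy controls appear in
no such table, so their moments are the package's own screening-negative
choices (age 64 ± 8, total PSA 1.2 ± 0.8 ng/mL, and so on), labelled
synthetic.

**Images.** Ultrasound speckle is emulated as multiplicative gamma noise
(unit mean; the shape parameter sets the variance) over a smooth
low-frequency background, with an elliptical ROI of at least 100 pixels.
No acoustic physics is simulated — the generator targets the statistical
contrast the texture features respond to, not the imaging chain. Within
the ROI, `texture_contrast` (default 1.5) shifts two texture parameters of
the T3b group relative to T2c: the gamma shape drops from 6 to
`6/(1 + contrast)` (more speckle variance) and a partial 3×3 smoothing
raises the correlation length. At `texture_contrast = 0` the group
distributions are identical, giving a usable null. The default of 1.5 was
chosen once as a moderately strong, realistic separation consistent with
the high radiomic discrimination the motivating study reports; it is not
tuned against any test.

**Time-intensity curves.** Refill curves follow
\(I(t) = A\,(1 - e^{-\beta t})\) on 40 time points with additive Gaussian
noise of SD `tic_noise_sd * A` (default 5%). Group parameters (A, β) are
(8, 0.35), (12, 0.5) and (16, 0.8) for healthy, T2c and T3b — perfusion
increasing with stage — with 15% lognormal inter-subject jitter. True
parameters are returned for recovery testing.

**Expression.** Counts are negative binomial with gene-wise means drawn
lognormal (median ≈ 100) and dispersion 0.1, a typical bulk RNA-seq value.
Planted structure: the six named staging biomarkers (FZD4, RPS7, RPL29,
miR-9-3p up in T3b; miR-374c-5p, miR-6510-3p down) shifted by
`2^de_log2fc` between T2c and T3b; `n_planted_de` stage-specific features
per stage (shifted versus healthy in one stage only, random sign); and
monotone-trend features (12 mRNAs decreasing healthy → T2c → T3b, 6 miRNAs
increasing, half the planted log2FC per step) that feed the network stage.
`de_log2fc = 1.5` matches the fold-change filter threshold with headroom.
A truth table records every planted effect.

**Interactions.** The edge list plants exactly 4 hub miRNAs (from the
monotone-increasing set, out-degrees 3/3/2/2) jointly covering 9 target
genes from the monotone-decreasing set, plus 30 degree-one decoy edges.

What the generator does *not* emulate: spatially heterogeneous tumors,
scanner/operator batch effects, library-composition artifacts, and
correlated gene-gene structure. Passing tests therefore demonstrate
algorithmic correctness and calibration under the stated model, not
clinical performance on real cohorts.

## Texture and wavelet features

`extract_all()` produces exactly 368 named features: 6 global first-order
features, 40 higher-order features — 9 GLCM, 13 GLRLM, 13 GLSZM and 5
NGTDM — and the same 46 features on each of 7 sub-bands of a two-level
discrete wavelet transform (322 = 7 × 46). Names are canonical
`subband-family-feature` strings (`cv2-GLSZM-LZHGE`, `NGTDM-Busyness`),
with the sub-band omitted for native features.

The higher-order inventory is not enumerated in the motivating study
beyond its size (40) and the members it names; the default here was chosen
to sum to 40, contain every named member, and use only standard Haralick,
run-length, size-zone and Amadasun–King definitions. The 7 × 46 wavelet
layout is adopted because it reproduces the printed 322 exactly with the
seven named sub-bands.

Numerical choices:

* **Quantization** (`quantize_roi()`): equal-width bins over the in-mask
  range, default Ng = 32; a constant region maps to level 1. All texture
  features are therefore invariant to affine intensity rescaling.
* **Masking**: co-occurring pairs with either pixel outside the ROI are
  dropped; runs and zones break at the mask boundary; NGTDM neighborhood
  means use in-mask 8-neighbors only. Whether a published analysis masks
  wavelet sub-bands is typically unstated; here sub-band features are
  masked, with the decimated mask keeping a cell only when *every*
  contributing original cell is in-mask (conservative; small ROIs can
  empty out at level 2, in which case the 46 features of that band are
  0-sentinels with a warning).
* **Aggregation**: co-occurrence counts are symmetrized and summed over
  the four distance-1 offsets before normalization (one matrix per
  family), matching the single-name-per-feature usage; run counts are
  likewise summed over the four directions, and the run percentage is
  normalized by `n_pixels × n_directions` so it stays in (0, 1].
* **Zones** are 8-connected components of equal level, labelled by a
  run-based union–find (verified against a breadth-first enumeration).
* **Degenerate sentinels**: correlation-type features on zero-variance
  input are 0; NGTDM coarseness is capped at 1e6 when its denominator
  vanishes; skewness/kurtosis of a constant region are 0.
* **Wavelet**: Haar by default (orthonormal, periodic extension, so total
  sub-band energy equals image energy to 1e-8, which the tests assert);
  Daubechies-2 is available. Dimensions must be divisible by 4.
* CEUS peak-frame selection (`peak_frame()`) takes the frame maximizing
  mean in-mask intensity; single frames bypass it.

## Perfusion parameterization

`fit_refill()` fits the mono-exponential destruction–replenishment model
\(I(t) = A\,(1 - e^{-\beta t})\) by Levenberg–Marquardt least squares,
initialized analytically (A from the maximum, β from a log-linear fit of
\(1 - I/A_0\)). The four reported features are RBV = A, RBF = A·β,
β⁻¹, and the refilling time RT = ln(10)/β (time to 90% of plateau). The
original study defers its perfusion definitions to prior work without
formulas; this parameterization is the standard one and makes RT distinct
from β⁻¹, as the downstream feature listings require. Units are arbitrary
intensity units (no calibration constant). Non-convergent fits or
non-positive parameter estimates return an explicit failure flag and are
excluded from correlation, never silent NaNs.

## Stepwise feature selection

`select_features()` implements correlation-based relevance–redundancy
selection. Relevance is |Pearson r| with the 0/1-encoded class. Step 1
selects the most relevant ("priming") feature; later steps select the
candidate maximizing relevance **minus** mean |r| with the retained set.
The stopping rule uses the literal score "mean |r| with retained features
plus relevance": the procedure terminates when
`score_t < drop_ratio * score_{t-1}` (default 0.5), at `max_features`
(default 20), or when features are exhausted.

Two genuinely open readings were decided as follows. The selection prose
("most closely related … but least related") demands redundancy
*penalization*, while the score sentence literally says "plus"; the
package uses minus for selection, computes the literal plus-score for
stopping, and exposes `redundancy_sign = "plus"` for the literal variant.
Second, the feature whose score triggers the sharp drop is itself *not*
retained — the drop is evidence that feature adds no value. "Dropped
sharply" has no published threshold, so it is the scale-free relative-drop
parameter `drop_ratio`. Ties are broken lexicographically, making the
trace a deterministic function of the input.

## Differential expression and the biomarker filter

Counts are normalized to log2(CPM + 1). Per feature, groups are compared
with Welch's unequal-variance t-test (vectorized over rows; verified
against `t.test`), with BH adjustment across features. The DE flag
requires `p < 0.05` *and* linear fold change beyond 1.5, the fold change
computed on linear CPM group means with a +1 pseudocount. The motivating
study's sequencing pipeline is out of scope here; a self-implemented,
calibrated test keeps the stage honest — under the null generator the
type-I rate at α = 0.05 stays inside the 99% binomial band (asserted over
600 features).

Stage-specific sets are pure Venn logic: T2c-specific = flagged in T2c vs
healthy but not in T3b vs healthy, and symmetrically. The all-tumor
comparison is recorded in the Venn report but does not subtract — the
"exclusively deregulated" reading excludes only the other stage. The
six-biomarker filter applies the same p/FC rule to the T3b-versus-T2c
comparison and reports directions. Gene-set enrichment is a one-sided
hypergeometric tail with BH across sets; set content (GO/KEGG or
otherwise) is supplied by the user as GMT.

## Integration

`correlate_features()` computes pairwise Pearson r between imaging
features and expression with two-sided t-distribution p-values, within a
stage subset by default (pooled correlations conflate stage effects; the
pooled mode is a parameter). Raw p-values are starred at 0.05/0.01 —
matching the starring convention of the motivating figures — with BH
starring available but off by default. `cca_ordination()` is the ter
Braak chi-square-standardized weighted regression + SVD form of canonical
correspondence analysis; with one binary constraint (stage) it yields
exactly one constrained axis. Its eigenvalues are cross-checked against
`vegan::cca` to 1e-8 in the tests; expression enters as linear CPM
(nonnegativity is required by the chi-square standardization).

## Classifier evaluation

Four feature sets — clinical, the six-biomarker transcriptomic panel,
radiomic (selected textures + the four perfusion features), and their
union — are evaluated with random forest, naive Bayes and RBF-SVM over 10
repeated stratified 70/30 splits. The split protocol is the package's
choice (the motivating study states only "10 runs"); stratification
protects the 13-patient T3b class. The same splits are reused across sets
and models (paired comparisons), features are z-scored with train-split
statistics only, and classifier hyperparameters are library defaults. The
AUC is a from-scratch Mann–Whitney midrank statistic, exact against
pair-counting enumeration. Held-out AUC is the only metric reported.

## Regulatory network

`trend_filter()` keeps features whose group means are strictly monotone
across healthy → T2c → T3b (decreasing for mRNA, increasing for miRNA),
each step exceeding a margin δ (default 0). Group-mean monotonicity was
chosen over per-sample monotonicity, which is unrealistically strict at
n = 13. `build_grn()` induces the miRNA → gene subgraph of a user-supplied
interaction table (the generator provides one; the original web resource
is out of scope), deduplicates edges, and ranks hubs by out-degree
(threshold 2), ties lexicographic. On the planted generator the 4 hubs
covering 9 targets are recovered exactly from noiseless group means.

## Problem sizes and reproducibility

The test suite and the acceptance script run the pipeline at reduced
scale — 64×64 images, Ng = 16, a few hundred expression features — which
exercises every code path of the full-scale analysis; the package default
is 128×128 with Ng = 32 (a 256×256 extraction takes about a second).
Every random draw descends from the single `study_config()` seed through
per-stream offsets, so reruns are bit-identical, and all tabular outputs
are written with fixed 10-significant-digit formatting so pipeline reruns
are byte-identical. `run_pipeline()` chains all stages and writes each
stage's artifact next to a fully resolved configuration.

## Known limitations

* The synthetic image model is statistical, not physical; absolute
  feature values have no clinical meaning.
* The higher-order feature inventory is a defensible reconstruction, not
  the authors' (unpublished) list; it is count-asserted and
  config-visible.
* The perfusion RT/β⁻¹ definitions are module conventions, flagged as
  such.
* Real-cohort quantities (AUCs of 0.887–0.998, 307/710 DEG counts) are
  not reproduction targets: they depend on private data. The package's
  claims are correctness, calibration and recovery of planted structure.
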