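---
title: "Deep image-derived risk scores for time-to-event prediction: models and design choices"
author: "DeepRadSurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep image-derived risk scores for time-to-event prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DeepRadSurv)
```

## The problem

In early-stage lung cancer treated with stereotactic body radiotherapy,
clinicians want pre-treatment predictions of four time-to-event endpoints:
overall survival (OS), recurrence-free survival (RFS), distant control (DC)
and local control (LC). Staging PET/CT offers anatomical (CT) and metabolic
(PET) views of each tumor. DeepRadSurv implements a two-arm modelling
framework over paired CT/PET tumor patches and clinical covariates:

* a **deep arm**: two small convolutional networks, one per modality, each
  mapping a 3-channel tumor patch to a scalar log-risk ("CT risk" and
  "PET risk"), trained by maximizing the Cox partial likelihood;
* a **hand-crafted arm**: 42 shape/intensity/texture radiomics features
  (21 per modality) reduced to 18 principal components.

Either predictor set is combined with age, gender, SUVmax and radiation
dose in a Cox proportional-hazards model with backward stepwise selection
at significance level 0.05; model quality is summarized by the test-set
concordance index. A random survival forest with logrank splitting and
Nelson-Aalen terminal-node hazards provides a non-proportional-hazards
alternative with variable-importance estimates.

## Statistical core

The hazard model is $h(t\mid x_i)=h_0(t)\exp(\beta_1\mathrm{CT}_i+
\beta_2\mathrm{PET}_i+\beta_3\mathrm{Age}_i+\beta_4\mathrm{Gender}_i+
\beta_5\mathrm{SUV}_i+\beta_6\mathrm{Dose}_i)$. Coefficients maximize the
partial likelihood; the baseline hazard is never estimated (out of scope by
design — the semi-parametric formulation exists to avoid it). Per-covariate
significance is the likelihood-ratio chi-square comparing the full
(unrestricted) fit against the fit with that covariate removed (restricted)
— the canonical test of nested Cox models, sometimes loosely called an
F-test of the coefficients. Backward
elimination repeatedly removes the covariate with the largest nested-test
p-value at or above $\alpha = 0.05$ and stops when all survivors are
significant; when nothing survives, downstream concordance is reported as
`NA` rather than a number produced by an unsupported model.

Tied event times use the Breslow convention throughout — the simplest
choice, consistent with the batch training loss, and exact for the
synthetic cohorts (whose continuous times are almost surely tie-free).

The concordance index follows the permissible-pair definition: pairs
$(i, j)$ with subject $i$'s event observed and $T_j > T_i$, scored by
whether the predicted ordering agrees. The default tie policy credits tied
predictions $1/2$ (Harrell's convention) so that a constant predictor
scores 0.5; a strict mode awarding ties 0 reproduces the literal indicator
definition and is used where exact equality with the enumeration oracle is
asserted. Risk-valued predictions are handled by an internal sign flip
(higher risk = earlier predicted time).

Kaplan-Meier curves, the Nelson-Aalen cumulative hazard
$\hat H(t)=\sum_{t_l\le t} d_l/Y_l$, and the two-group logrank test follow
their textbook definitions (`survival` supplies the fitting machinery; the
cumulative hazard and concordance are computed by this package and
cross-checked against `survival` in the test suite). Risk-group cut-offs
are maximally selected logrank thresholds: candidate cuts are midpoints of
consecutive sorted unique covariate values whose groups both hold at least
10% of subjects, and the maximizing chi-square is reported with its
*uncorrected* 1-df p-value. Because the threshold is chosen to maximize the
statistic, that p-value is optimistic; no multiplicity correction is
applied, and the reported value should be read as descriptive.

## The deep branches

Each branch is `conv 3x3/32 + ReLU -> maxpool 2x2 -> conv 3x3/32 + ReLU ->
maxpool 2x2 -> FC 32 + ReLU -> FC 1 (linear)`, with 'same' spatial padding,
seeded Glorot-uniform initialization and plain SGD. The training objective
is the negative Cox partial log-likelihood with risk sets restricted to the
SGD batch (batch size 32), normalized by the number of events in the batch
and stabilized by log-sum-exp centering; event-free batches are skipped
(they define no likelihood and contribute no gradient). Batch-restricted
risk sets are the standard minibatch construction for this loss and are an
approximation to the full-cohort likelihood.

Production-scale settings are learning rate $10^{-5}$ with 2000 epochs.
The package's experiments run at desk scale: 150 epochs with learning rate
$2\times 10^{-3}$, chosen once so that the total SGD path length (epochs
$\times$ rate) is comparable to the production setting on cohorts of a few
hundred cases. Arithmetic is float32 — the standard deep-learning precision
— with im2col convolution lowering onto BLAS `sgemm`; all randomness
(initialization, epoch shuffles) is drawn from R's RNG so a single seed
reproduces training bit-for-bit.

Optional pre-training uses a convolutional auto-encoder per modality whose
encoder is exactly the risk net's conv/pool trunk; the decoder (a design
gap we fill explicitly) is nearest-neighbor $\times 2$ upsampling followed
by two 3x3/32 ReLU convolutions and a linear 3x3 head back to 3 channels,
trained 100 epochs under the same SGD on a *disjoint* unlabeled cohort.
The trunk weights then initialize the risk networks.

## Preprocessing

Tumors are cropped to the tight ROI bounding box and centered on a square
zero-intensity canvas — 80 px for CT, 28 px for PET at defaults, the sizes
that cover the largest tumor in the emulated cohort. Odd centering
remainders are biased toward the top-left — centering needs a convention
and this one is fixed and tested. Channels are either the middle
tumor slice with its two immediate neighbors, or a multi-scale triple with
margins 0/10/20 px per side (clipped at the image border). Margin crops
that still fit the canvas are zero-padded — which keeps the margin-0
channel identical to the plain crop-and-pad path — and crops larger than
the canvas are bilinearly downscaled with aspect preserved: the minimal
rule that makes different-sized scales stackable while leaving the
no-margin path untouched.
Intensities are min-max scaled to $[0,1]$ per modality using training-set
statistics only.

## Hand-crafted radiomics

Per modality and middle slice: 7 shape, 8 intensity and 6 texture features
(42 per case across CT+PET). The shape-feature counts (1 area-regularity,
2 perimeter-regularity, 4 symmetry values) follow the classical lung-CT
radiomics feature sets, which are usually cited without explicit formulas;
our concrete definitions —
isoperimetric ratio $4\pi A/P^2$, convex-hull-perimeter ratio plus radial
coefficient of variation, and Jaccard overlaps with reflections about four
centroid axes — realize those counts and are documented at the
function level. Perimeters use Vossepoel-Smeulders step weights (0.980
axial, 1.406 diagonal), which correct most of the raster overestimation so
a rasterized disc scores near 1. Intensity features are the eight listed
order statistics and moments, with population-form standard deviation and
excess kurtosis; constant regions define skewness and kurtosis as 0.
Texture features derive from a symmetric gray-level co-occurrence matrix
quantized to 32 bins over the ROI range and averaged over the four unit
offsets; quantization depth and offsets are configuration with tested
defaults. Normalized entropy divides by
$\log_2(\mathrm{levels}^2)$, the entropy of the uniform co-occurrence
distribution.

The 42 features go through a PCA fitted on training cases only (z-scored
with training means/scales; 18 components by default, with the component
cap `min(n-1, p)` enforced — a fixed default rather than a variance
threshold, so runs are comparable across cohorts). PCA
is fit jointly across modalities; a per-modality fit would be an equally
defensible reading, and the joint choice maximizes shared-variance capture.

## Random survival forest

Trees are grown on bootstrap samples with replacement; at each node `mtry` (default
$\lceil\sqrt p\rceil$) randomly chosen covariates are scanned over midpoint
split candidates whose daughters both hold at least `min_node_size` cases,
and the split maximizing the logrank chi-square is taken, up to depth 10
with node size 10 (production: 10,000 trees; tests: $\le 200$). Terminal
nodes store the Nelson-Aalen cumulative hazard of their in-bag members; an
event-free node has a CHF of exactly zero. Prediction averages terminal
CHFs over trees on the grid of distinct training event times; the
cumulative-CHF risk score at horizon $h$ (e.g. 24 months) sums the ensemble
CHF values at grid points up to $h$. The out-of-bag error is 1 minus the
concordance of OOB risk scores — the conventional survival-forest error
measure. VIMP uses
random daughter assignment: when an OOB case meets a split on the probed
variable it is sent to a random daughter, and VIMP is the resulting
increase in OOB error. On this definition VIMP is an error difference and
lives in $[-1, 1]$; implementations that report VIMP on other scales are
not comparable without renormalization.

## The synthetic cohort generator

No patient data ships with the package; a seeded generator emulates the
statistical structure the pipeline assumes, and its defaults are fixed
study conditions, not tuning knobs:

* 132 cases by default with 1-3 tumors each (probabilities 0.87/0.10/0.03,
  giving ~150 tumors per 132 cases); ages centered at 74.65 (52-92),
  lognormal SUVmax, doses around 100 Gy-equivalent.
* Each tumor is a rotated ellipse with uniform semi-axes, rendered with a
  flat base intensity plus uniform texture noise of amplitude "roughness"
  on an almost-black background, on both modalities (PET geometry is the
  CT geometry scaled by 28/80; PET intensity tracks SUV). Neighbor slices
  shrink the cross-section by 20%.
* The hidden latent risk of a tumor is the sum of within-cohort z-scores
  of area, mean ROI intensity and roughness — one driver per downstream
  feature family (size, first-order intensity, texture), so every arm has
  signal to find.
* Event times are exponential with rate
  $\lambda_0\exp(\beta_{img}\cdot\mathrm{latent}+
  \beta_{clin}^T z(\mathrm{clinical}))$; censoring is the minimum of an
  independent exponential and a 60-month administrative horizon, with
  simultaneous event/censoring times (measure zero) recorded as censored.
  Defaults $\lambda_0 = 0.02$/month and censor rate 0.015/month put the
  median observed follow-up near 27 months, the follow-up scale of the
  emulated cohort; the generative family itself is a modelling choice
  (any proportional-hazards family would do, and the exponential has
  closed-form checks).
* OS, RFS and DC records are drawn per case from the index (highest-SUV)
  tumor's risk; LC records are drawn per tumor with tumor-specific risk,
  mirroring the endpoint's tumor-level definition. For modelling, the
  tumor-level LC endpoint is represented per case by its index tumor's
  record, keeping one covariate row per case across all outcomes.

What the generator does **not** emulate: lung anatomy and surrounding
tissue, scanner physics and reconstruction artifacts, segmentation error
and inter-observer variability, correlated clinical covariates, or
non-proportional hazards. Tests passing on these cohorts therefore
demonstrate that the estimators and the pipeline are implemented
correctly and recover planted structure — not that the models transfer to
real PET/CT data.

## Numerical and engineering choices

* Coordinates are R-native 1-based inclusive ranges; the bounding-box and
  padding examples fix the exact pixel conventions.
* Newton fitting of Cox models is delegated to `survival::coxph`
  (tolerance $10^{-9}$, up to 100 iterations); divergent or separated fits
  raise errors rather than returning unstable coefficients.
* The maximally selected cut-off scan and the forest splitter share one
  vectorized logrank sweep; ties in the maximum resolve to the smallest
  threshold.
* Stepwise ties (two covariates with identical worst p-values) drop the
  first in column order — deterministic by construction.
* The float32 network is bit-reproducible for a fixed seed on a fixed
  build; loss curves are logged per epoch.

## Desk-scale experiment sizes

The test suite and the worked examples run deliberately scaled-down
problems: cohorts of 24-300 cases (tiny 16/8-px canvases for orchestration
tests, full 80/28 canvases for the recovery experiment), 150-epoch network
training, forests of 15-200 trees, and 10-seed replications for
frequency-style claims. The end-to-end recovery experiment uses a 200-case
cohort with a strong planted image-driven hazard
($\beta_{img} = 1$ per latent-risk unit, clinical coefficients zero) —
under these conditions the oracle c-index of the true latent risk is well
above 0.8 (asserted in the test suite), leaving the deep arm realistic
headroom to clear 0.70 when it works.
The production-scale settings (2000 epochs, $10^{-5}$ learning rate,
10,000 trees) remain available through the spec objects.

## Known limitations

* The maximally selected cut-off p-value is uncorrected (see above).
* Batch-restricted Cox risk sets bias the loss slightly relative to the
  full likelihood; with 32-case batches and a few hundred cases the effect
  is small, but it is an approximation.
* The hand-crafted shape definitions are one concrete reading of a count
  specification; other readings (e.g. different symmetry axes) would give
  different feature values while preserving the counts.
* LC modelling collapses multifocal cases to their index tumor; a fully
  tumor-level analysis would need per-tumor covariate rows and clustered
  standard errors, which are out of scope.
* Concordance indices below 0.5 are reported as computed, without sign
  flipping; interpretation is left to the caller.
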