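---
title: "Automated nuclear morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated nuclear morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem

Nuclear pleomorphism — variation in the size and shape of tumor nuclei — is
a malignancy criterion in tumor grading. Pathologists estimate it by eye on
a three-tier (anisokaryosis) or two-tier (shape irregularity) scale, and
those estimates reproduce poorly between observers. The alternative is
morphometry: segment each nucleus in a region of interest (ROI) of known
scan resolution, measure size and shape descriptors, summarize them per ROI,
and validate the summaries as prognostic tests against patient survival.
`nucmorph` implements that pipeline: synthetic ground-truth generation,
segmentation, instance extraction, morphometric profiling, accuracy
evaluation, a manual-subsampling protocol, and the outcome statistics.

This vignette explains the models behind each stage, the tunable parameters
and their defaults, the numerical choices, and what the synthetic fixtures
can and cannot show.

## The synthetic-data model

`generate_nucleus_image()` is the package's source of ground truth: every
downstream stage is tested against fixtures whose true segmentation,
areas and shapes are known exactly.

Nuclei are ellipses with a low-order radial Fourier perturbation. An area
`A` is drawn from a log-normal law parameterized by its mean and SD in µm²
(defaults 30 and 10 µm² — a realistic tumor-nucleus scale at which the 7 µm²
noise floor is far in the left tail); the axis ratio is uniform on
[1, 2.5]; the contour radius is modulated by harmonics 2–5 with maximum
relative amplitude `irregularity` (default 0.1), which perturbs solidity
and eccentricity while leaving area nearly unchanged (the area bias of a
mean-zero radial perturbation is second order). The default canvas is
1590 × 1192 px at 0.25 µm/px — a 0.1185 mm² field with 4:3 aspect ratio, the
0.5-HPF ROI geometry of modern grading guidelines — with ~600 nuclei, a
realistic density for a carcinoma ROI.

Placement is rejection sampling. With `overlap_fraction = 0` bounding
circles must be disjoint, which guarantees pairwise-disjoint rasterized
instances; the sampler saturates near one nucleus per ~4000 px², so the
generator reports (with a warning and the `n_requested` field) when it
cannot place everything. A configurable fraction of placements is allowed to
intersect earlier nuclei; overlapping pixels go to the later label, which is
exactly the undersegmentation failure mode a mask-level pipeline has to
live with. Masks are produced by rasterizing the polygons themselves
(pixel-center, boundary-inclusive), so the polygon and raster ground truths
are consistent by construction, not by a second algorithm.

Rendering is deliberately minimal: darker foreground with per-channel
Gaussian noise on an H&E-like palette. Segmentation tests need contrast, not
texture; no claim of photorealism is made, and results on these fixtures
bound what the classical segmenter can do on clean input, not its
performance on real tissue (chromatin texture, stain variation, touching
nuclei in thick sections are all absent).

Survival cohorts follow a proportional-hazards model: event times are
exponential with rate `λ₀·exp(xᵀβ)` per case, administratively censored
uniformly and capped at a follow-up horizon (default 250 days). Because the
hazard structure is planted, Cox estimation can be tested as parameter
*recovery* rather than against another library. Rating panels discretize a
latent continuous severity score at per-rater cutpoints after per-rater
noise — the mechanism by which identical morphology ends up in different
categories across observers.

## Segmentation

`reference_segment()` is the deterministic mask source: channel-mean
grayscale, Gaussian smoothing (`sigma_px = 1`), a single global threshold by
between-class-variance maximization (Otsu), hole filling. A constant image
yields an empty mask rather than an error. Its known limitation is inherited
from global thresholding: on an image containing *no* nuclei but some noise,
Otsu will still split the noise; the pipeline is intended for ROIs selected
to contain tumor.

The learned-backend ingredients are implemented as pure functions so that
any trainable model can be dropped in:

* `compute_weight_map()` implements
  `w = w_c + w₀·exp(−(d₁+d₂)²/(2σ²))` with `d₁`, `d₂` the distances to the
  nearest and second-nearest instance. Weights peak in the thin background
  gaps between adjacent nuclei — the pixels a segmenter must get right to
  avoid merging instances. Defaults `w₀ = 10`, `σ = 5 px`, class weights 1:
  these are explicit package defaults, chosen to match common practice for
  border-separation maps, not values fixed by any reference analysis.
* `weighted_focal_loss()` is `mean(w · α_t (1−p_t)^γ (−log p_t))` with
  defaults `γ = 2`, `α = 0.25`. With `γ = 0`, `α = 0.5` it reduces to half
  the mean binary cross-entropy, which the tests use as an anchor.
  Probabilities are clamped at `1e-7` and confident-wrong pixels reported.

`train_tiny_segmenter()` demonstrates the loss end to end: a logistic pixel
classifier on RGB + 5×5 local-mean + intensity features, full-batch gradient
descent, one gradient step per epoch, epoch selection by validation loss
(falling back to the last epoch, with a warning, when no validation set is
given). It is honest about what it is — a desk-scale backend that reaches
Dice ≥ 0.75 on held-out fixtures in seconds — not a substitute architecture
claim.

## Instance extraction and morphometry

`label_components()` uses iterative minimum-label propagation with
8-connectivity by default (the common choice for blob labeling;
4-connectivity available, and the checkerboard disambiguates the two in the
tests). Labels are renumbered in scan order, so the labeling is a pure
function of the mask. The `< 7 µm²` filter removes noise objects by strict
inequality: an object of exactly 7.0 µm² is a nucleus. Border-touching
instances are retained for algorithmic morphometry — only the manual
protocol excludes margin-cut nuclei — with an `exclude_border` flag for the
alternative.

Shape descriptors follow the moment/hull definitions:

* **Eccentricity** comes from the covariance of the pixel centers plus the
  unit-square self-covariance `I/12` (each pixel treated as a 1×1 square).
  The correction makes a single pixel a circle (e = 0) and keeps collinear
  sets strictly below 1, and vanishes relative to λ for nuclei of realistic
  size. Against analytic ellipses with axes ≥ 15 px, area is within 2% and
  eccentricity within 0.02 of truth.
* **Solidity** divides the pixel count by the pixel count of the rasterized
  convex hull of the pixel centers. Because hull vertices are integer pixel
  centers, the inclusion test is exact, and a convex rasterized shape has
  solidity exactly 1 — so `1 − solidity` is a true zero for regular nuclei.

The per-ROI profile uses sample (n−1) SDs and adjusted Fisher–Pearson
skewness (the defaults of mainstream statistical software); "largest 10%"
means the `⌈0.1·n⌉` largest instances; percentiles interpolate linearly
between order statistics. With fewer than 2 (SD) or 3 (skewness) instances
those entries are `NA`. Karyomegaly percentages use two thresholds,
defaulting to 42.3 and 50.5 µm² — the 90th percentile and twice the median
of a large annotated reference distribution of tumor nuclei —
recomputable from any reference sample via
`derive_karyomegaly_thresholds()`.

## The manual protocol

`grid_plan()` partitions the ROI into 5 × 6 equal cells and fixes the
meandering order: left→right on row 1, right→left on row 2, and so on from
the upper-left corner. The geometry of the meander is not uniquely
determined by "meandering from the upper left"; boustrophedon by rows is the
package's choice and is configurable through the plan object.
`assign_to_grid()` gives each annotation to the earliest cell in meander
order containing any of its pixels — an annotation straddling a grid line
counts once, in the cell reached first — and excludes margin-cut
annotations. `grid_subsample()` accumulates whole cells until the count
reaches 100, then completes the current cell; the subset is always a prefix
of the cell order, sized in `[100, 100 + max cell count − 1]`, which on
realistic fixtures lands in the low hundreds — the same band a human
annotator following the rule produces.

## Accuracy evaluation

Pixel Dice is `2|P∩G|/(|P|+|G|)`, defined as 1 for two empty masks. Object
matching is the one unstated-but-critical choice of any detection score: the
package uses greedy one-to-one matching by descending IoU with an IoU ≥ 0.5
criterion (the community standard for nucleus detection), pluggable to a
centroid-containment criterion. Greedy-by-IoU is compared against exhaustive
maximum matching on small random instances in the tests and never exceeds
it. RMSE-to-range divides the per-parameter RMSE by the range of the
ground-truth values across the evaluated cases, making errors comparable
across parameters with different units.

## Prognostic statistics

`prepare_cohort()` encodes the follow-up rules at a horizon (default 250
days): tumor deaths within the horizon are events; unrelated deaths are
censored at the death time; cases lost to follow-up within the horizon are
excluded; survivors are censored at the horizon. Binary labels for ROC are
defined only where the outcome at the horizon is known (event before it, or
survival past it) — a 46-case cohort with 8 lost, 10 tumor deaths, 3
unrelated deaths and 25 survivors yields exactly 10 positives and 25
negatives, with 38 cases in the survival set.

Choices where the convention was genuinely open:

* **AUC** is the tie-corrected rank-sum probability; its CI uses the
  asymptotic DeLong variance, with a stratified bootstrap fallback when the
  variance degenerates (e.g., a single-member class). Larger score = worse
  prognosis by default, with a direction flag per test.
* **Threshold selection** anchors all dichotomized tests at sensitivity
  ≥ 70%: among candidate thresholds (midpoints of adjacent distinct scores
  plus ±∞, positive when score ≥ threshold), keep those with Sen ≥ 0.70,
  take the minimal attained Sen, maximize Sp, and break ties toward the
  larger threshold. The anchor makes specificities comparable across tests.
* **`precision_from_rates()`** reconstructs integer confusion cells from
  rounded Sen/Sp percentages and the class sizes by nearest-integer
  rounding — the arithmetic that connects published Sen/Sp/precision
  triples.
* **Cox regression** uses the Efron tie approximation (the default of
  mainstream survival software, and accurate for the heavy ties a fixed
  horizon creates) with Wald CIs; a monotone partial likelihood (complete
  separation) is reported as non-estimable rather than as a huge number.
* **Kappa interpretation** rounds to two decimals before binning into
  slight/fair/moderate/substantial/almost-perfect, so a kappa of 0.204 is
  "slight" — rounding after, not before, would contradict the bin edges.

Null calibration is part of the test suite: over 200 seeded null cohorts
(n = 100) the 95% Wald CI covers HR = 1 at 90–99%, and a planted
`log HR = ln 3` is recovered within [2.5, 3.6] at n = 2000.

## Problem sizes and determinism

Test and acceptance fixtures use canvases from roughly 250 × 200 to
2000 × 1500 px with 8–500 nuclei — sizes chosen so the whole suite runs in
well under a minute per module while every property still has room to fail.
All generators are pure functions of their spec (including its seed): the
same spec yields byte-identical TIFF/JSON fixtures, and the acceptance
script derives every seed from its single `--seed` argument.

## Known limitations

* The fixtures do not emulate chromatin texture, stain variability,
  out-of-focus regions, or non-neoplastic cell classes; passing tests bound
  algorithmic correctness, not clinical performance.
* Global-threshold segmentation assumes a bimodal intensity histogram; an
  ROI without nuclei but with noise will produce spurious foreground.
* Undersegmentation (merged touching nuclei) is represented in the
  generator's overlap mode but no splitting post-processor is provided —
  abnormal size/shape of merged objects is exactly the signal the
  morphometry is supposed to measure, which makes filtering it out
  self-defeating.
* Multivariable survival models and spline-smoothed rater-calibration
  curves are out of scope.
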