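---
title: "Methods: automated pap-smear analysis with papscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated pap-smear analysis with papscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(papscreen)
```

## Overview

`papscreen` implements an automated screening pipeline for bright-field
cervical cytology (pap-smear) images. A slide image passes through six
stages:

1. **Enhancement** — weighted grayscale conversion
   (`0.3 R + 0.59 G + 0.11 B`) followed by contrast-limited adaptive
   histogram equalization (CLAHE).
2. **Scene segmentation** — a trainable pixel-level classifier assigns
   every pixel to nucleus, cytoplasm, background or debris.
3. **Debris rejection** — a three-phase sequential gate removes non-cell
   objects by size, shape, then texture.
4. **Feature extraction** — 29 nucleus/cytoplasm morphometric features per
   retained cell.
5. **Classification** — fuzzy C-means clustering with a Bayesian
   cluster-to-class defuzzification yields a 7-class call
   (superficial, intermediate, columnar; mild, moderate, severe dysplasia;
   carcinoma in situ) and the binary normal/abnormal diagnosis.
6. **Slide diagnosis** — a slide is positive when at least `min_abnormal`
   cells are called abnormal (default 1).

A synthetic-data module generates labelled feature tables and rendered
slide scenes with exact ground truth, so the entire pipeline is testable
without any external image corpus.

## Image enhancement

Grayscale conversion keeps real values; quantisation to 8 bits happens
only on file export. CLAHE is applied tile-wise (default 8 x 8 tiles) with
a normalised clip limit of 2.0 — each tile histogram is clipped at twice
its mean bin height before equalisation, which darkens nuclei and makes
cytoplasm boundaries conspicuous without amplifying background noise to
the same degree. The clip limit and tile grid are configurable
(`enhance()`); an image with zero dynamic range is returned unchanged,
since there is no contrast to redistribute.

A consequence worth knowing: CLAHE is a *local* operation, so absolute
intensity values after enhancement are not comparable with the raw
acquisition scale. All intensity features downstream are therefore
measured on the enhanced image for both training and test material, which
keeps them internally consistent.

## Pixel-level scene segmentation

Following the trainable-segmentation paradigm, the user scribbles example
pixels of each scene class and a probability random forest (200 trees,
seeded, single-threaded for determinism) is fitted on a multi-scale filter
bank evaluated at the scribbled pixels only. The bank covers the filter
families named for this problem: noise-reducing Kuwahara and bilateral
filters, Sobel gradient magnitude, Hessian eigenvalues at two scales,
a Gabor bank (4 orientations x 2 wavelengths), and six local rank/texture
statistics (mean, variance, median, maximum, minimum, entropy) at three
radii — 34 feature planes in the default configuration. The original
toolchain exposes a stack of 226 features; the families, not their exact
enumeration, carry the information, so the bank is configurable
(`filter_bank()`) and its configuration is embedded in the trained model
and checked at inference.

An optional box-smoothing of the per-class probability maps before the
argmax is available (`smooth_radius`); it is off by default because label
speckle is repaired more precisely at the object level (below), and
smoothing measurably blurs the nucleus boundary of small cells — on
rendered scenes a radius-2 smoothing tripled the interquartile error of
the recovered nucleus areas. The label map invariant (label = argmax of
the stored probabilities, probabilities sum to 1) holds with or without
smoothing. Argmax ties break by class declaration order, nucleus first.

Candidate objects are 8-connected components of nucleus-labelled pixels,
after a morphological closing (radius 2) that reconnects nuclei split by
residual speckle; the touching cytoplasm component is attached, and
nucleus components sharing one cytoplasm are merged — one cell owns one
cytoplasm, so its nucleus fragments are not independent candidates.
Segmentation quality is summarised by the Zijdenbos similarity index
(`zsi()`), `2|A∩B|/(|A|+|B|)`.

## Debris rejection

Three gates run strictly in order; an object is examined by a later gate
only if it passed all earlier ones, which keeps each decision
low-dimensional and the rejection report interpretable.

* **Size.** Retain iff `area_min <= area <= area_max` (inclusive), with
  defaults 625 and 85,267 in calibrated area units. The unit system is
  that of the training-class statistics (pixel counts at the 0.201 µm/px
  acquisition scale); images rendered or acquired at another scale carry
  an `area_factor` so measured pixel counts are compared on the same
  scale as the printed thresholds. The upper bound sits one standard
  deviation above the mean whole-cell size of the largest class, so a
  small fraction of genuinely large superficial cells is sacrificed by
  design to bound the search space.
* **Shape.** The perimeter-area descriptor is gated as normalised
  circularity `4*pi*A/p^2 ∈ (0, 1]`, rejecting above 0.97 (too circular —
  droplets, bubbles) or below 0.15 (fibres, folded edges). The raw
  `p^2/A` value is also stored: as printed, a `p^2/A` band of
  (0.15, 0.97) is unsatisfiable since `p^2/A >= 4*pi` for any region, so
  the normalised form is the only reading under which the published
  thresholds are meaningful. Perimeter follows a fixed convention: the
  outer contour polygon through pixel centers, 8-connected tracing,
  diagonal steps counting `sqrt(2)` (a 10 x 10 square measures 36).
* **Texture.** For every object pixel, complex Zernike moments `A_nl`
  (orders `n <= 9`, default 25-px window, evaluation on the inscribed
  unit disk) are computed on the enhanced image and their magnitudes
  averaged over pixels and (n, l) pairs. Homogeneously stained nuclei
  produce a narrow score distribution; debris with strong stain-intensity
  variation scores far outside it. The threshold is either a fixed number
  or `AUTO`: scores above the batch median plus 3.5 robust (MAD) spreads
  are rejected. An Otsu split of the score distribution was evaluated
  first, but its split placement is unstable on small batches that
  contain a single outlying object (it tends to group the most textured
  genuine cell with the debris mode); the median + MAD rule implements
  the same principle — a narrow cell mode with outlying debris — in a
  robust form, and degrades gracefully to "retain all" on homogeneous
  batches. With fewer than two scored objects AUTO retains all and warns.

## Feature extraction

The 29 features (`feature_names`) follow the conventional morphometric
definitions; where the tabulated names leave the operation open, the
package fixes them as follows: shortest diameter = twice the maximum of
the distance transform (largest inscribed circle); longest diameter =
minimal enclosing circle (exact, computed on the convex hull);
elongation = shortest/longest; roundness = area over the longest-diameter
circle area; eccentricity from second central moments; solidity = area
over convex hull area; maxima/minima = counts of regional extrema plateaus
under a disc structuring element of radius 3; histogram features (mean,
SD, variance, entropy, energy, smoothness) on the 256-bin normalised
histogram of enhanced intensities, with `0 log 0 := 0` and smoothness
`1 - 1/(1+sigma^2)` on intensities scaled to [0, 1]; relative position =
nucleus-to-cell centroid distance over the cell's longest radius. The
nucleus-to-cytoplasm ratio is `NA/(NA+CA)` as tabulated (the printed N/C
column of the source statistics matches this formula only approximately;
the formula is taken as written). A cell without a detected cytoplasm
carries `NA` cytoplasm features (excluded from training rather than
imputed) and N/C ratio 1.

## Fuzzy C-means classification and Bayesian defuzzification

Memberships follow

$$m_{ik} = \frac{1}{\sum_{j=1}^{c} (d_{ik}/d_{jk})^{2/(q-1)}}$$

with Euclidean distances in z-scored feature space (training-split
statistics; constant features get unit scale). Centers update as
membership^q-weighted means; the objective \(\sum m_{ik}^q d_{ik}^2\) is
non-increasing and iteration stops at a maximum center shift below 1e-5
(cap 300 iterations). The default operating point is c = 25 clusters and
fuzzifier q = 1.0930 — the published operating values; with q this close
to 1 the memberships are nearly hard, so the update is evaluated through
logarithms for numerical stability, and a point coinciding with a center
receives full membership there. Initialisation is seeded farthest-point
(k-means++-style) sampling; `restarts` independent starts keep the best
objective. A zero-distance tie and any argmax tie break by declaration
order.

Defuzzification builds a probabilistic cluster-to-class model: training
points hard-assign to their maximum-membership cluster; the
cluster-conditional likelihood of class \(A_i\) is the Laplace-smoothed
occupancy fraction \((n_{ij}+\alpha)/(n_i+\alpha c)\) (α = 1 by default —
with it, sparsely populated clusters pull their posterior toward the
class priors rather than toward noise); priors are proportional to class
mass; and the posterior \(P(A_i \mid B_j)\) is the normalised Bayes
product (the published denominator is written as \(B_j\); it is
implemented as the normalising constant). A new point's class posterior
is its membership-weighted mixture of cluster posteriors; the class is
the argmax and the binary diagnosis groups the first three classes as
normal, the rest abnormal.

## Feature selection

`sa_select()` searches feature subsets by simulated annealing with a
wrapper fitness: the stratified k-fold (default 10) cross-validated
misclassification rate of the FCM classifier fitted on the subset.
The schedule is geometric (T0 = 1, alpha = 0.95, 20 moves per
temperature, stop at 1e-3); a move flips one uniformly chosen bit and is
redrawn if it would empty the subset; worse moves are accepted with
probability `exp(-delta/T)`. The fitness is a pure, seeded function of
the subset, so evaluations are memoised and the best-ever state is
returned with the full trace. The published 18-feature selection is
shipped as `reference_subset` — selection is data- and seed-dependent, so
the constant is a reference default, not a reproduction target. An
optional stability report (`sa_stability()`) reruns the search (default
60 reruns) and reports per-feature selection frequencies.

## Synthetic data: what it emulates and what it does not

`class_stats()` ships the per-class means and SDs (nucleus area,
cytoplasm area, N/C ratio, brightness, perimeters) of the training
material; these defaults are the study conditions and are not tuned.
`gen_feature_table()` draws the seven tabulated features as independent
truncated Gaussians (rejection sampling at physical bounds: positive
areas and perimeters, ratios in [0, 1], brightness in [0, 255]) and
synthesizes the remaining features consistently with near-elliptical
geometry. The carcinoma-in-situ cytoplasm perimeter is shipped as printed
(28 ± 67) but flagged, because it is inconsistent with that class's
cytoplasm area; the renderer derives perimeters from areas instead.

`render_scene()` rasterises each cell as an elliptical cytoplasm with an
interior elliptical nucleus, shaded by the class brightness draws on a
bright background with additive Gaussian noise (SD 4), and adds debris
engineered to trip specific gates: specks below the lower area bound,
fibres below the circularity band, and coarse speckled blobs with
outlying Zernike scores. Rendering conventions chosen once and
documented: linear scale 0.25 relative to the calibrated unit system
(areas in units = pixels × 16, so full multi-cell scenes stay tractable;
the debris gates receive `area_factor = 16`); axis ratios uniform in
[0.45, 0.58], because rasterised near-circular ellipses at small pixel
sizes measure circularity above the 0.97 gate under the fixed perimeter
convention; nucleus-area draws truncated below at 250 units so nuclei
remain segmentable at this scale; whole cells kept above 1600 units for
stable discrete shape; an 8-px placement margin between objects (the
generator does not emulate touching or overlapping cells, which the
pipeline does not attempt to split). For the compact classes (columnar
and the four abnormal grades) the cytoplasm area is derived from the
drawn N/C ratio rather than drawn independently: the printed area and
ratio marginals are mutually consistent only if the two areas are
correlated, and the ratio is the tighter, more diagnostic marginal.
Intensities follow the staining physics rather than raw independent
draws: nuclei carry coarse chromatin mottling (2-px blocks, SD 9), each
nucleus is at least 25 gray levels darker than its own cytoplasm, and
the nucleus ([20, 110]) and cytoplasm ([115, 180]) envelopes are kept
disjoint — grayscale rendering has no hue channel, and an absolute
intensity overlap between one cell's cytoplasm and another's nucleus is
unresolvable by local pixel features (measured directly: such scenes
defeat any classifier trained on other slides, because adaptive
equalization additionally makes the enhanced intensity scale
composition-dependent across slides).

What passing tests on this material does and does not show: the
generator reproduces the *marginal* class statistics with clean staining
and simple geometry. It does not emulate overlapping or folded cells,
uneven illumination, stain batch effects, or the correlation structure of
real morphometry (an optional knob couples nucleus area with N/C ratio).
Accuracy on rendered scenes is therefore an upper bound on what the same
models would achieve on clinical material, and is used here to verify the
machinery, not to claim clinical performance.

The default classifier subset for the synthetic benchmark is
`stats_features` — the seven tabulated features. They are the
discriminative core of the generated data; the remaining synthesized
features are deliberately class-uninformative jitter, and including them
degrades distance-based clustering (that observation is also why wrapper
feature selection exists in the pipeline). On real material the published
18-feature `reference_subset` is the shipped default.

## Numerical choices and degenerate inputs

* Zernike evaluation restricts to the inscribed unit disk; pairs with
  `n - |l|` odd are identically zero and excluded; moment magnitudes are
  rotation-invariant (checked to 1e-6 relative under 90° rotations) and
  match a direct double-sum evaluation to 1e-8 relative.
* Borders are reflected for windowed texture, replicated for
  convolution.
* The ROC sweep uses the unique scores as thresholds; AUC by trapezoid
  equals the Mann-Whitney concordance.
* Percentages in metric reports are rounded half-up to 2 decimals at
  reporting only.
* Degenerate contracts: a single-pixel object has no contour and raises
  a shape error; both-empty masks make the ZSI undefined; an empty
  feature subset, a class with fewer members than folds, single-class
  truth for the ROC, and unfitted models all raise errors naming the
  condition.
* Every stochastic step (scribble sampling, forest fitting, FCM
  initialisation, SA proposals, generators) is seeded; re-running with
  the same seed is bit-reproducible.

## Problem sizes used in the shipped checks

The test-suite benchmark renders two training scenes of 105 cells each
and one test scene of 140 cells plus debris (about 1200-1300 px square at
the default scale) and runs the full pipeline in a few minutes on one
core; unit tests use one small mixed scene (roughly 450 px square) shared
across files. These sizes were chosen as the smallest at which the
class geometry and the gate behaviour are all exercised meaningfully.

## Known limitations

* Overlapping and touching cells are not split; a cytoplasm shared by
  several nuclei is treated as one candidate object.
* The 226-filter stack of the original toolchain is emulated by family
  coverage, not reproduced filter-for-filter.
* The texture-gate threshold is data-driven (or user-fixed); the source
  states the principle but no number.
* Class statistics are marginals; real joint structure is richer, and
  columnar cells genuinely overlap the dysplastic classes in this
  feature space, which bounds attainable binary accuracy.
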