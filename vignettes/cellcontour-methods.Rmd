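---
title: "Outline-learning cytoplasm segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline-learning cytoplasm segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcontour)
```

## The segmentation problem

High-content screening produces two-channel fluorescence fields: an actin
channel showing cell cytoplasm and a DNA channel showing nuclei. Cytoplasm
segmentation in such data is hard for reasons that are structural, not
incidental: cells cluster into clumps whose mutual boundaries are barely
visible, the actin signal varies strongly between and within cells, cell
interiors are inhomogeneous enough to resemble background locally, and the
images are low-contrast and noisy. Global intensity thresholds fail on such
data, and force-splitting heuristics destroy legitimate multinuclear
phenotypes.

`cellcontour` implements a three-block pipeline that addresses these
failures separately:

* **Block A — initial cytoplasm/background separation.** A multi-scale
  coefficient-of-variation (COV) enhancement turns the *stability* of a
  pixel under progressive Gaussian smoothing into a segmentation cue,
  so dim-but-stable cytoplasm separates from noisy background even when
  their raw intensities overlap.
* **Block B — outline detection as pixel classification.** Cell-to-cell
  boundaries, including invisible ones inside clumps, are detected by a
  sparse L1-penalized logistic regression classifier over a large generic
  feature bank; the penalty performs feature selection, so the deployed
  model usually needs fewer than ten features.
* **Block C — nuclei-contextual post-processing.** Detected outlines are
  thinned to 1-px contours and applied to the initial mask; the resulting
  regions are split or merged using the nuclei as markers, without ever
  force-splitting a region that has no outline evidence.

## Block A: scale-space COV enhancement

The Gaussian scale space of an image $f$ is the family
$L(\cdot,\cdot;t^2) = g(\cdot,\cdot;t^2) * f$ with $g$ a rotationally
symmetric Gaussian of standard deviation $t$; $t = 0$ is the image itself.
Per pixel, the package computes the dispersion of $L$ across the scale list
divided by its mean plus an offset $\varepsilon$:

$$f_{COV} = \frac{\mathrm{disp}_t\,L(\cdot,\cdot;t^2)}{\mathrm{E}_t\,L(\cdot,\cdot;t^2) + \varepsilon}.$$

Background and outline pixels change quickly under smoothing (high COV);
cytoplasm interiors are stable (low COV). The enhanced image
$f_{enh} = f + (2^b - 1 - f_{COV}^{norm})$ (with $f_{COV}$ min–max
normalized to the representable range of a $b$-bit image) therefore pushes
cytoplasm high and background low, after which a 256-bin Otsu threshold
separates the two classes. Small components below a profile-specific
minimum area are removed (8-connectivity).

Parameters and defaults:

* `scales`: `0:6` for cytoplasm and for nuclei at the same magnification;
  `seq(0, 3, 0.5)` for lower-magnification nuclei of ~25 px diameter cells,
  where wider kernels would weld neighbouring objects together.
* `min_object_area`: 600 px (cytoplasm-scale objects) or 100 px (small
  nuclei).
* `epsilon = 1`: guards the division at near-zero mean intensities.
* `variant`: the dispersion is the standard deviation across levels
  (`"std"`, a true coefficient of variation, the default) or the variance
  (`"var"`). Both are implemented because the two definitions are equally
  defensible readings of the method; empirically they segment the synthetic
  fields almost identically (both are exercised in the tests). The
  expectation over the stack uses the population convention (divide by the
  number of levels) since the stack is a complete family, not a sample.

Numerical choices: Gaussian kernels are truncated at $4\sigma$ and
renormalized (mass loss $< 10^{-4}$); all neighborhood operations in the
package use reflect padding so borders carry no dark-frame artifacts;
$f_{enh}$ is linearly rescaled back to $[0, 2^b-1]$ before Otsu (how
overflowing values are handled is otherwise unspecified, and rescaling
preserves the ordering Otsu depends on); a constant COV image is treated as
all-zero with a warning. The Otsu step itself carries one deterministic
tie-break: when the between-class variance has several local maxima within
12% of its global maximum — which happens on enhanced nuclei channels,
where a wide mid-level background competes against a small bright object
class and the argmax flips from realization to realization — the highest
threshold among them is chosen, the only reading compatible with the
enhancement's objects-end-high polarity. Curves with a single dominant
peak (the usual cytoplasm case) are unaffected.

### Pre-processing cascade

Three filters run before Block A, in order:

1. **CLAHE** — contrast-limited adaptive histogram equalization on an
   8×8 tile grid, 256-bin tile histograms, bilinear blending. The clip
   limit is expressed as a fraction of the tile pixel count
   (`clip_fraction = 0.01`), the same normalization MATLAB-style
   implementations use; clipping prevents over-amplification of
   homogeneous regions, so a constant image passes through unchanged.
   Histograms span the image's occupied intensity range: a low-contrast
   12-bit image (say two tones 100/110) must end up spread over the full
   range, which full-range bins cannot deliver because both tones fall
   into one 16-level-wide bin.
2. **Opening by morphological reconstruction** — the marker is the erosion
   of the image by a flat disc of radius 5 px (a pixel belongs to the disc
   iff its center is within the radius); the marker is grown back under the
   image by geodesic dilation to stability (Vincent's hybrid algorithm,
   compiled). Unlike plain opening this preserves the topology and exact
   heights of plateaus wider than the disc while flattening narrow specks,
   which evens out the varying actin signal.
3. **Saturation stretch** — the lowest and highest 1% intensity quantiles
   are clipped and the remainder mapped affinely onto $[0, 2^b-1]$.

## Block B: the feature bank and the sparse classifier

The bank contains 290 per-pixel features from 11 filter families
(counts in parentheses): Gaussian low-pass, $\sigma = 3,5,\dots,49$ (24);
integrated intensity, box sums $3,5,7,9$ (4); Laplacian of Gaussian,
$\sigma = 3,5,\dots,49$ (24); difference of Gaussian (5); morphological
top-hat and bottom-hat, box kernels $3,5,\dots,49$ (24 + 24); local binary
pattern (8, 1) and local contrast (2); local variance, $3,5,\dots,49$ (24);
min/median/max order statistics, $3,5,7$ (9); 13 Haralick co-occurrence
statistics at window sizes $5,7,\dots,15$ (78); Gabor magnitudes at kernel
sizes $5,7,\dots,15$ × frequencies $\{1/4, 1/2, 3/4\}$ cycles/px ×
orientations $\{0, \pi/4, \pi/2, 3\pi/4\}$ (72).

Feature names follow the grammar `FAMILY[_param…]_KxK` (`VAR_3x3`,
`MIN_7x7`, `IMOC2_9x9`, `GABOR_f0.25_th0.75pi_5x5`), which is the canonical
link between the bank, serialized models and this document.

Design decisions where the family definitions were genuinely open:

* *Difference of Gaussian* carries no published parameter grid; it is
  defined as the 5 consecutive differences of the $\sigma \in
  \{3,5,7,9,11,13\}$ smoothings, consistent with the family's $\sigma$
  ladder.
* *Haralick*: gray levels quantized to 32 bins over the image range;
  symmetric co-occurrence at distance 1 pooled over 4 directions; the 13
  classic statistics with natural-log entropies, sum variance centred at
  the sum entropy as in the original definition. Quantization level count
  is not specified anywhere authoritative; 32 bins keeps 15×15 windows
  (≤ 900 pair samples) from spreading the matrix too thin.
* *LBP*: plain 8-neighbor radius-1 code (not rotation-normalized) plus the
  population variance of the 8 neighbors as the contrast measure.
* *Gabor*: envelope $\sigma = (K-1)/4$, unit aspect ratio, complex response
  reported as magnitude (phase handling is unspecified; magnitude makes
  responses at $\theta$ and $\theta + \pi$ coincide, which the tests pin).

### The classifier

Outline (vs non-outline) probability follows a logistic model; the
coefficients maximize the penalized binomial log-likelihood

$$\tfrac{1}{N}\textstyle\sum_i \big[y_i \log p_i + (1-y_i)\log(1-p_i)\big] - \lambda \lVert\beta\rVert_1$$

via iteratively re-weighted least squares with cyclic coordinate descent on
the quadratic approximation, warm-started along a 100-value $\lambda$ grid,
log-spaced from $\lambda_{max}$ (the smallest $\lambda$ with all
coefficients zero; there the intercept is exactly the log class ratio)
down to $10^{-3}\lambda_{max}$. The intercept is unpenalized. Features are
standardized to zero mean and unit population variance before fitting;
coefficients are stored on the standardized scale together with the
standardization parameters, so serialized models are self-contained.

Training data are 500 outline and 500 non-outline pixels sampled uniformly
without replacement from a manually outlined (or synthetic ground-truth)
field. Model selection is 10-fold cross-validation, folds stratified by
class, binomial deviance loss. The default rule is the one-standard-error
rule — the sparsest $\lambda$ within one SE of the CV minimum — because
models in that band change the classification imperceptibly while being
much sparser; `rule = "min"` is available.

Numerical choices: convergence is judged on the weighted squared
coefficient change (tolerance $10^{-7}$), the standard coordinate-descent
stopping rule; a max-absolute-change rule at the same nominal tolerance was
measured to cost ~30× more sweeps on this bank's heavily correlated columns
(adjacent-$\sigma$ Gaussian features are nearly collinear) with no visible
effect on the solution, whose KKT violations stay below $4\times10^{-3}$.
Probabilities are clamped to $[10^{-5}, 1-10^{-5}]$ inside IRLS, as is
conventional, to keep weights bounded away from zero under
quasi-separation.

Two transcribed reference models ship with the package
(`inst/models/eq8_tc1.json`, 7 features for HeLa-type 12-bit fields;
`inst/models/eq9_tc2.json`, 5 features for Kc167-type fields). These are
applied to **raw** feature values (identity standardization) and carry
`link_sign = +1`, i.e. $p = 1/(1+e^{+\eta})$, honouring their published
form, whereas freshly fitted models use the textbook $p = 1/(1+e^{-\eta})$
(`link_sign = -1`). The sign is a serialized model property, so both
conventions coexist without ambiguity; a regression test pins the
probability each shipped model assigns to an all-zero feature vector.
Classification thresholds the probability at 0.5 by default, and at test
time only the model's selected features are computed.

## Block C: nuclei-contextual post-processing

The classifier's raw output is accurate but coarse: thick outlines,
misclassified interior pixels, broken contours. Post-processing proceeds:

1. **Filtering** (`filter_outlines`): outline pixels on nucleus interiors
   are removed (a nucleus pixel can never carry a cell outline); small
   holes in the initial mask are filled, holes containing a nucleus always;
   the inverted initial mask is unioned with the outlines so the
   cell/background transition always counts as outline evidence. The
   hole-filling and the inversion-union are applied in that fixed order.
2. **Skeletonization** (`skeletonize_outlines`): Guo–Hall thinning to 1-px
   strokes. Thinning of this type preserves topology *and* line endpoints,
   so non-connected branches — fragments of real outlines interrupted by
   noise — survive and can later bridge gaps. A final pass removes any
   residual 2×2 foreground block by deleting simple non-end points.
3. **First-stage segmentation**: 8-connected components of
   `initial & !skeleton`.
4. **Split and merge** (`split_merge`): regions are partitioned by
   reconstruction from nucleus markers. One-nucleus regions are closed
   (disc radius 3) to smooth interiors. Multi-nuclei regions have their
   adjacent skeleton branch fragments dilated (disc radius 2) to bridge
   gaps, are re-thinned and re-cut; pieces inherit nuclei by majority
   overlap. A multi-nuclei region with no outline evidence is *never*
   force-split — that would translate nuclei over-segmentation into
   cytoplasm over-segmentation and would destroy multinuclear phenotypes.
   Nucleus-free fragments are merged into the adjacent nucleus-bearing
   region whose union has the largest solidity (area / convex-hull area;
   cells are mostly convex), ties to the lowest label, for 3 passes;
   fragments never reached by a cell are dropped.
5. **Cleanup**: holes below 50 px are filled, diagonal junctions between
   distinct labels (h-connectivity) are removed, labels are compacted to
   1..K in raster-scan order.

The structuring sizes (bridge radius 2, closing radius 3, 3 merge passes,
50 px hole ceiling) are engineering defaults exposed in
`postprocess_config()`: radius 2 bridges 1–4 px outline gaps without
welding distinct contours, radius 3 removes branch stubs without merging
across the 1-px cuts.

## Evaluation protocol

`match_objects` implements greedy maximum-overlap matching: benchmark
objects, visited in descending area order, claim the segmented object of
largest pixel overlap; the pair's own pixel-level F-measure must reach
`fm_threshold = 0.6` for a true positive, and a claimed object is removed
from further matching. Unclaimed segmented objects are false positives.
Only one-to-one, one-to-none and none-to-one correspondences can result,
so `TP + FN` equals the benchmark count and `TP + FP` the segmented count.
Precision, recall and F-measure are reported at full precision; 2-decimal
round-half-up is applied only for display. Cytoplasm matching never
consults the nuclei image: nuclei over-splitting does not always imply
cytoplasm over-splitting, so using it would bias the score. The visiting
order (descending area, ties by label) is a deterministic choice where the
protocol is otherwise silent; large objects dominate overlap ambiguity.

## The synthetic generator

`synth_generate` emulates the challenge conditions the pipeline targets:
Fourier-perturbed elliptical cells with spiky protrusions, per-cell
multiplicative gain (0.7–1.3), a radial interior intensity dip (30% of the
plateau at the rim), a smooth illumination gradient, additive Gaussian
noise (sd 150 on a 12-bit scale, SNR ≈ 9 at the dimmest plateau), and a
nucleus ellipse inside each cell. Ground-truth labels and 1-px closed
outlines are emitted exactly.

The defaults — 12 cells of radius 18–28 px on a 192×192 field at overlap
level 0.35 — put roughly half of the field under cells. That density is
deliberate: benchmark fields for this kind of method are chosen so that
most of the area is covered with cells, and the CLAHE + COV front end
relies on it (on nearly empty fields, tile-wise equalization lifts the
background and the enhanced histogram loses its bimodality; we measured
the initial segmentation dropping from F ≈ 0.99 at ~50% coverage to
F ≈ 0.25 at ~10% coverage). Placement is sequential rejection sampling on
the pairwise center-distance constraint; an infeasible layout is retried
from a derived sub-seed for up to 10 deterministic rounds before the
configuration is rejected. All randomness flows from one master seed with
per-cell substreams indexed by cell counter, so adding cells does not
perturb earlier cells and identical configurations are bit-identical.

What the generator does **not** emulate: optics (no PSF, no shot noise, no
defocus), texture inside cytoplasm beyond the radial dip and noise, and
membrane staining (the boundary cue between touching cells is the
intensity valley where both cells' dips meet). Passing the end-to-end
tests therefore shows the pipeline's machinery is sound under the stated
conditions — it does not certify performance on any real dataset.

## Problem sizes used by the test-suite and acceptance runs

The end-to-end checks train on one 192×192 generated field (500 + 500
pixels, all 290 features, 10-fold CV) and evaluate five held-out fields of
the same configuration — about 60 cells — asserting an object-level
F-measure of at least 0.85 with counts pooled over the fields, the same
pooling the published evaluation tables use. The support-recovery study uses 20 replicates
of 200 samples × 50 features with 3 active coefficients. Oracle-equivalence
checks (reconstruction, Otsu, order statistics, Haralick) run on 32×32
images against brute-force per-pixel implementations. These sizes were
chosen as the smallest at which the respective effects are stable.

## Known limitations

* The COV front end assumes fields substantially covered by cells; sparse
  fields degrade it (see above). The nuclei channel is more robust because
  nuclei are compact and bright.
* The shipped reference models apply to raw feature values of images
  preprocessed exactly as described here; they are transcriptions, not
  refits, and their features are computed by this package's definitions of
  the Haralick and Gabor families, which may differ in inessential
  normalization constants from other implementations.
* Solidity-guided merging assumes mostly convex cells; highly dendritic
  morphologies would mis-merge.
* Evaluation is pixel-overlap based; boundary-distance metrics (Hausdorff,
  ASSD) are out of scope.
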