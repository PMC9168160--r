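---
title: "Exudate detection in fundus images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exudate detection in fundus images: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exudatekit)
```

## The problem

Diabetic retinopathy damages retinal microvasculature; leaking vessels
deposit lipids and proteins that appear in colour fundus photographs as
exudates. *Hard* exudates are dense, sharply delimited and saturated
yellow; *soft* exudates (cotton-wool spots) are fluffy, whitish pale yellow
and may carry a slight blue tinge. Because hard exudates are among the
earliest visible signs of the disease, a pipeline that finds them, measures
the largest lesion and raises a flag when it is too big is a useful
screening primitive. `exudatekit` implements that pipeline end to end, with
a synthetic image generator standing in for clinical datasets so every
claim the package makes is checkable by its own test suite.

## Denoising

The noise model addressed is sensor grain (additive Gaussian) plus impulse
("salt and pepper") corruption. Denoising is a fixed composition: a 3×3
weighted linear smoothing filter first, then a median filter.

Two reference kernels ship with the package. `table2_printed()` stores the
reference weight pattern verbatim; its entries sum to 17/16 because the
bottom-right weight is 1/8 where a symmetric Gaussian-like pattern would
have 1/16, so it brightens a constant image by about 6%. The default for
`smooth_linear()` is therefore `table2_normalized()` — the same weights
divided by their sum — which preserves constant images exactly. Both are
selectable wherever a kernel is accepted.

Numerical choices, used consistently everywhere in the package:

* **Border policy**: edge replication for both convolution and median
  windows. Zero padding would darken the already-dark retinal rim.
* **Rounding**: half-away-from-zero, then clipping to [0, 255]. R's default
  banker's rounding would make the impulse-response test values depend on
  parity.
* **Convolution orientation**: true convolution (kernel flipped), so that
  the response to a unit impulse reproduces the printed weight layout; the
  distinction matters because the printed kernel is not symmetric.
* **Masked ("stratified") median**: when a mask is given, only in-mask
  pixels are rewritten and the window median ignores out-of-mask
  neighbours. The pipeline's default mask is the yellow exudate colour
  range — the one colour the downstream stages care about — with
  `mask = "full"` as the whole-image fallback.

### Denoising order and the colour box (a known red)

The acceptance suite keeps one failing assertion on purpose: that
colour-box recall of planted exudate pixels *improves* after `denoise()` on
an impulse-corrupted image. It cannot, in this design, and the failure is
informative enough to document rather than hide.

The colour box requires R ≥ 235. Smoothing an isolated pepper pixel
(value 0) spreads it across its 3×3 neighbourhood: with the normalized
kernel an edge-adjacent neighbour keeps only 1 − 2/17 of its red value,
about 225 for a 255 red — already outside the box. The median filter then
sees a window in which five or more of nine values are corrupted the same
way and cannot restore them. Independently, blending at the blob rim
removes roughly one ring of pixels (20–22% of a 10 px-radius blob) at
*zero* noise. Writing the rim fraction as $\rho$ and the per-impulse pixel
cost as $c \approx 4.5$, recall after denoising is at most
$(1-\rho)(1-cf)$, which is below the corrupted input's recall $1-f$ for
every corruption fraction $f \in (0,1)$ once $\rho > 0$ and $c > 1$.
Measured on the generator (seed 19, 192 px, four hard blobs): 0.78 vs 1.00
at $f=0$, 0.56 vs 0.90 at $f=0.1$, 0.19 vs 0.68 at $f=0.3$; the printed
(brightening) kernel and windows 5/7 do not change the ordering. A
median-only pass (no prior smoothing) repairs recall to above 0.97, but the
smoothing-first order is part of the stated contract, so the assertion
stays red. What *is* true, and tested green, is that `denoise()` reduces
mean absolute error against the clean image.

## Hue equalization

Hue is defined as the green/red channel ratio per pixel, on channels scaled
to [0, 1]. Pixels whose scaled red value is at or below `rT = 0.1` are
excluded: on the [0, 1] scale 0.1 genuinely removes dark-red pixels,
whereas on a 0–255 scale it would remove almost nothing — that is how "a
very small positive threshold" must be read for the guard to do anything.

Equalization multiplies the green channel of valid pixels by
`H_des / Hc_average` and repeats until the mean ratio is within `tol`
(default 1e-3) of the target `H_des` (default 0.5160). Two details matter:

* The correction accumulates on the *original, unquantized* green channel.
  Requantizing between iterations and then applying a sub-half-level
  multiplicative step rounds away to nothing, and the iteration fixes
  itself permanently at the wrong average (observed: stuck at 0.51499
  against a 0.5160 ± 0.001 contract). Accumulating the scale factor lets
  successive steps compound until pixels actually move.
* Invalid pixels receive no correction, and red and blue are never touched,
  so validity is invariant across iterations and the procedure is a
  contraction: absent clipping it converges in one step.

The target can also be supplied per image; the constant 0.5160 is the
default operating point.

## Segmentation and severity

The hard-exudate colour range is the per-channel box spanned by
RGB(255,128,0) and RGB(255,178,102), widened by a tolerance (default 20) on
each side. The printed hex labels of that range (#ff8800, #ffcc99) decode
to slightly different triples; the decimal triples were adopted because the
reference colour table's G (128–178) and B (0–102) columns agree with them,
and the synthetic generator samples hard-exudate colours from the same box
so the detector and the stated world agree.

Components are 8-connected; the dropped-component floor is `min_pixels = 5`
because the ellipse fit needs five points. The fitted ellipse is the
second-moment (inertia-equivalent) ellipse: centroid centre, axes from the
eigen-decomposition of the coordinate covariance, semi-axes
$2\sqrt{\lambda}$ — the scaling under which a uniformly filled ellipse
recovers its own semi-axes. A 1/12 quantization variance per coordinate
keeps single-pixel rows and thin lines away from degenerate fits, and the
minor semi-axis is floored at half a pixel for collinear sets. Contour
least-squares fitting was rejected: for blobs of tens of pixels the contour
is mostly rasterization noise, while second moments are stable.

`find_max_elliptical_region()` maximizes ellipse area with deterministic
tie-breaks (pixel count, then topmost-leftmost centroid).
`assess_severity()` uses a strict inequality, so a lesion exactly at the
threshold is not an emergency. The default threshold is 1% of the circular
field-of-view area (`severity_threshold()`): the "minimal concerning area"
is never quantified in the source material, and 1% of the FOV disc is the
order of magnitude at which a single hard-exudate plaque is no longer
subtle on clinical images. Canny edges (Sobel gradients, non-maximum
suppression, hysteresis at 0.1/0.2 of the maximum gradient) are available
as an optional mask refinement but are deliberately not in the default
path: the source mentions edge support without thresholds, and the colour
box alone already meets the recovery tolerances on the stated world.

Hard/soft labelling is a two-sided colour rule: hard iff mean blue ≤ 80 and
saturation (max−min)/max > 0.3. The blue ceiling separates the saturated
yellow band from whitish/blue-tinged soft exudates; the saturation guard
sends gray (desaturated) means to soft.

## Enhancement

* `histogram48()`: 48 equal-width bins over [0, 255] — coarse enough that
  each bin is a distinct small value range, and normalized by total pixel
  count.
* `glcm()`: uniform quantization to `levels` (default 8) gray levels, pair
  counts at an offset, optional symmetrization/normalization.
* `ahe()`: tile-based (8×8) histogram equalization of the HSV value
  channel.
* `clahe_rd()`: CLAHE applied independently to each RGB channel, clip limit
  in multiples of the uniform bin height (default 2), 8×8 tiles, bilinear
  blending of tile mappings. "RGB density" is read as per-channel
  operation: of the three enhancement routes, only this one leaves the
  exudate *colour* information intact — the GLCM route collapses to
  grayscale and the AHE route to HSV value — which is why the ranking test
  asserts CLAHE-RD gives the best colour-selection F1 on noisy synthetic
  fixtures.

Two numerical conventions make the degenerate cases exact: a tile whose
histogram occupies a single bin maps identically (so constant images pass
through both `ahe()` and `clahe_rd()` unchanged), and as the clip limit
tends to zero the clipped-and-redistributed histogram tends to uniform,
whose mapping is the identity — the no-budget limit returns the input.

The contrast-gain property is asserted on an *under-exposed* copy of the
synthetic fundus. On a full-brightness image the exudates already sit at
the top of the intensity range, and any equalization can only compress the
gap; low-contrast captures are the regime the method exists for.

## The GMPR activation and the patch CNN

`gmpr_prelu()` scans a pre-activation sequence in order. Positive values
pass unchanged and update the pair (p₁, p₂) of the last two positives; a
non-positive value is replaced by √(p₁·p₂) once both exist, and by
0.01·x before that. The geometric mean lies between its two sources, so
the substitution interpolates rather than extrapolates — the property the
test suite asserts on random sequences. Zero counts as "next value is
zero" and is substituted.

Design decisions where the description was open:

* **Scan order** is row-major within each feature map, with state reset at
  the start of every forward pass per map.
* **History** is taken from pre-activations (the values the unit actually
  receives), not post-activation outputs.
* **Gradient**: the substitution is forward-only; backward treats the
  substituted output as constant in x (zero gradient there), with the
  leaky fallback keeping slope 0.01. The source gives no gradient; this
  choice keeps training stable and makes the activation a drop-in for ReLU
  on the positive part.

The classifier is four blocks of (3×3 convolution, 16 maps → optional
per-map standardization → activation → 2×2 max pool), a 256-unit dense
layer and a 4-way softmax over {hard_exudate, soft_exudate, other_lesion,
background}. The conv kernel is 3×3 (only the pooling size is specified as
2×2 upstream). The reference input is 240×240 (15×15 maps after four
pools); the desk-scale default is 48×48, and inputs not divisible by 2⁴
are zero-padded up. Training is mini-batch Adam (lr 1e-3), deterministic
given the seed, implemented in base R via im2col matrix multiplication —
no deep-learning framework exists in the supported environment, and the
activation's sequential semantics would not fit a stock framework op
anyway. On 200 separable synthetic patches the default (GMPR) network
passes 0.9 training accuracy within 15 epochs in under two minutes on one
CPU; the split fractions are configurable and default to 70/15/15 because
the source's printed split counts are internally inconsistent.

## Binned survival-fraction ROC

The evaluation table takes ordered per-bin (true, false) counts,
accumulates them, and sets x_k = 1 − cumT_k/T, y_k = 1 − cumF_k/F with the
anchor (1, 1) prepended. These columns are labelled "FPR" and "TPR" in the
reference layout even though both are survival fractions of their own
class totals — the implementation follows the numbers, not the labels,
because only this reading reproduces every printed cell. The AUC is the
left-endpoint rectangle rule Σ (x_k − x_{k+1})·y_k, each segment's area
attributed to its upper row; it is the only rule consistent with the
printed per-segment contributions, and it dominates the trapezoidal value
whenever y is non-increasing (also tested). A trapezoidal mode is
available behind a flag. Reported precision is six decimals. Degenerate
inputs (all-true or all-false) are rejected: one axis's survival fraction
would be undefined. Confusion-matrix metrics report a zero-denominator
metric as `NA`, never 0.

## The synthetic world

`generate_fundus()` draws: a circular field of view of radius 0.48·size on
black; a radially shaded reddish-brown retina (base RGB (168, 72, 46),
±6 texture); a bright optic disc (radius 0.07·size, offset toward one
side) when enabled; `vessel_count` dark curved vessels radiating from the
disc; `n_hard` hard ellipses (semi-major 6 px to 5% of the image side,
colours uniform in the hard box) and `n_soft` soft ellipses
(RGB ≈ (250, 235–250, 150–210)), placed without mutual overlap and clear
of the disc, erroring after 100 failed placements. Noise — Gaussian
(σ = 2 default) plus salt-and-pepper (fraction 0.002 default) — is applied
only after the ground-truth masks and ellipse records are frozen. Defaults
(256 px, 4 hard, 2 soft, mild noise) were chosen once as a plausible
moderate-retinopathy frame: lesions a few hundred px² on a quarter-frame
FOV, noise at the edge of visibility.

What a green test on this world establishes: geometric correctness
(planted ellipse recovery within 2 px / 15% area), colour-pipeline
correctness (≥95% recall at zero noise), ordering properties (noise
degradation, enhancement ranking), and trainability on separable classes.
What it does not establish: performance on clinical images — real fundus
photographs have illumination gradients, optic-disc false positives,
drusen, laser scars and camera-specific colour casts that this generator
deliberately does not model, and the upstream headline accuracies on
clinical datasets are out of scope by design.

`generate_patch_dataset()` plants one structure per grid cell and crops one
patch per cell, so patches are provably non-overlapping and exactly
balanced; `other_lesion` patches are hemorrhage-like dark-red blobs so the
four-class problem is not a three-class problem in disguise.

## Known limitations

* No optic-disc localization or vessel segmentation; the disc is a known
  false-positive source for bright-lesion detectors and is only avoided by
  construction in the synthetic world.
* The reference colour table's "contrast ratio" column is carried as opaque
  metadata; it matches no standard contrast formula and is not computed.
* PNG/JPEG I/O needs the optional `png`/`jpeg` packages; the built-in
  format is netpbm PPM.
* The GMPR gradient choice (straight-through zero at substituted
  positions) is one of several defensible conventions; others (e.g.
  differentiating through the geometric mean w.r.t. p₁, p₂) were not
  explored.
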