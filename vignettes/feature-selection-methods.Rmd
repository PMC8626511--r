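---
title: "Selecting small, stable feature vectors for histology segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting small, stable feature vectors for histology segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pixel classifiers for stained histological sections are trained on
hand-crafted feature stacks: color-space transforms plus windowed texture
descriptors computed at several spatial scales. The stacks are large (114
features per pixel under the default parameterization here), and on
whole-slide images every retained feature costs 4 bytes per pixel of memory
and a proportional share of extraction time. Classical feature-selection
algorithms can shrink the stack, but their selections are notoriously
unstable: retrain on a second dataset and a different subset comes back.

`fmpvselect` implements a two-step, brute-force selection framework built
around a stability criterion, the *feature Median Position Value* (fMPV),
and validates every selection under a two-fold swap design (direct
validation, DV: train on set A, test on set B; cross validation, CV: the
swap).

## The fMPV criterion

All combinations of features up to a size limit are evaluated with a
weighted random forest (WRF), scored by the F-score of the class of
interest, and sorted into a single table by decreasing F-score. For a
feature $f$, its *position vector* is the list of 1-based ranks of every
combination containing $f$; the fMPV is the median of that vector. A low
fMPV means $f$ concentrates in well-ranked combinations — rank acts as a
penalty, and the median summarizes the whole distribution of a feature's
appearances rather than a single best hit, which is what makes the
criterion stable. The same definition pools to coarser scales by merging
member rank vectors (with multiplicity): feature *families* (the
non-oriented variants of one descriptor at one scale, e.g. the four
orientations of a Gabor wavelength's real part) and feature *spaces*
(RGB, HSV, XYZ, LAB, MEAN, VAR, GABOR, HARALICK, LBP).

Exhausting all $2^{114}-1 \approx 2\times 10^{34}$ subsets is impossible, so
the search is size-limited and split in two steps:

1. **Family selection** (size limit 2 over all features). A family is kept
   if (P1) its pooled fMPV is below the mean per-feature fMPV and (P2) its
   space's fMPV is below the mean space fMPV, independently in DV and CV;
   the selected families are the intersection of the two conditions. P1 is
   stated ambiguously at the family scale in the original description; the
   default here scores the family as a pooled unit (`mode = "pooled"`),
   with a strict per-member reading available as `mode = "strict"`.
2. **Feature aggregation** (size limit 4 over the retained features).
   Starting from the full step-2 table $L_0$, each round selects the
   feature with the lowest fMPV *computed on the surviving rows* and then
   discards every combination not containing all selected features.
   Positions keep their original global ranks: the list is filtered, never
   re-sorted. At the final permitted round the criterion switches to the
   best F-score among the surviving maximal-size combinations; that last
   iterate probes the size limit but is **not** itself selectable — the
   returned vector is the best-F-score iterate among the fMPV-selected
   rounds, with ties going to the smaller vector. If DV and CV select
   different vectors, the one with the higher mean table F-score is
   returned (`reconcile()`), tagged so the disagreement is visible.

## The feature bank

`feature_bank_config()` fixes the bank: 12 colorimetric features (RGB
pass-through, HSV, CIE XYZ, CIE L\*a\*b\*), local mean and variance over a
disk, riu2 local binary patterns at four radii, four Haralick GLCM
statistics (angular second moment, correlation, contrast, variance) per
direction and radius, and a Gabor bank (4 wavelengths x 4 orientations x
real/imaginary). Window radii in the two staining presets span the stained
object's size range up to roughly twice its maximum radius — windows larger
than the object are what let windowed statistics distinguish small stained
objects from larger stain accumulations.

Conventions the original description leaves open are fixed as follows:
sRGB primaries with D65 white point; XYZ via the standard sRGB
linearization and L\*a\*b\* from that XYZ; H scaled to $[0,1)$; all textural
features computed on the CIE Y luminance of the linearized RGB; GLCM over
16 gray levels binned uniformly on the full intensity range, unit offset,
square window of side $2r+1$ with both pixels of a pair inside the window,
symmetrized and normalized, correlation defined as 0 when the window
variance vanishes; LBP with $P = 8$ bilinear-interpolated samples and
$s(x) = 1$ for $x \ge 0$ (with a $10^{-10}$ interpolation tolerance so flat
regions code uniformly); Gabor kernels truncated at $\pm 3\sigma$; reflect
padding everywhere, implemented by index folding so radii may exceed the
image extent. Where the source text's aspect-ratio value conflicts with its
parameter table, the table (1.5) is used.

Filtering is done by direct shift-and-accumulate summation rather than FFT
products. This is deliberate: direct summation makes every output pixel a
fixed-order function of its neighborhood only, which is what guarantees
that tiled computation of a large image is bit-identical to whole-image
computation (`segment_large_image()` checks that the tile overlap is at
least the active features' support halo before computing anything).
Windowed GLCM counts are rectangle sums of integer indicator images via
integral images — exact in double precision — so the same guarantee holds
for the Haralick maps.

## The segmenter

`train_wrf()` wraps `ranger` with per-class weights (the class of interest
is up-weighted at split evaluation, the standard weighted-random-forest
device for minority classes). Defaults follow the optimized operating point
for the low-contrast staining preset: 100 trees, maximal depth 10,
neuron-class weight 2.0. `optimize_wrf()` reproduces the sequential
optimization design — depth first at weight 1, then the weight of the class
of interest at the chosen depth — scoring candidates by the mean of the DV
and CV F-scores (the combiner is not stated in the source; the mean is the
symmetric choice) with ties to the smaller value. The F-score pools pixels
over the whole test set rather than averaging per image; per-image
averaging is not implemented because the pooled reading matches a
pixel-level evaluation of one large virtual section.

Two implementation details matter for reproducibility. First,
`ranger`'s prediction breaks vote ties from R's global RNG; predictions here
pin the tie-break seed to the model's training seed, making every pipeline
stage a pure function of (data, seed). Second, each combination evaluated
by the brute force derives its own seed from the global seed and a hash of
the feature names, so results are independent of evaluation order and
worker count.

## The synthetic data generator

No histological data ship with the package; `generate_sample()` is the test
substrate. It emulates a DAB-stained section: a near-white background, a
textured light-brown tissue region (thresholded low-frequency random
field), small dark-brown elliptical neurons with internal speckle texture,
and larger, darker, internally smooth artifact blotches. Three design
choices carry the science:

* **Brown is encoded as correlated RGB** with the largest tissue/stain
  contrast in the blue channel, so blue-channel discriminativeness can
  *emerge* from the data rather than being hard-coded.
* **Artifacts share the neuron chromogen.** They model non-specific
  concentrations of the same stain, so their color range overlaps the
  neurons' (per-blob variation is a correlated stain-intensity factor,
  0.8–1.25 by default). Color separates stain from tissue; only spatial
  scale and internal homogeneity separate neuron from artifact. This gives
  the task the complementary-information structure real staining has —
  without it, every color channel is individually sufficient, combination
  tables become noise-dominated near-ties, and no selection method (this
  one included) can be expected to pick stably among interchangeable
  features. Under the default configuration a full-bank WRF reaches a
  neuron F-score above 0.95, single features range from about 0.4 to 0.85,
  and two- to three-feature combinations recover most of the full-bank
  score.
* **Degenerate configurations are first-class.** Setting all texture
  amplitudes to zero yields a color-only task; giving tissue and neurons
  equal-amplitude sinusoidal gratings of different wavelengths
  (`*_texture_wavelength_px`) yields a texture-only task with matched
  per-pixel intensity distributions. The test suite checks that the fMPV
  ranking is dominated by colorimetric spaces in the first case and by
  textural spaces in the second. The grating option exists because
  unstructured per-pixel noise is *not* a pure texture contrast: it changes
  the per-pixel marginal distribution, which a deep tree on a raw color
  channel can exploit.

What the generator does not emulate: optics (blur, chromatic aberration,
vignetting), scanner stitching artifacts, staining gradients across a
section, nuclear substructure, or touching/overlapping cell clusters.
Passing tests therefore demonstrate the correctness and stability of the
selection machinery on a controlled task with a known feature hierarchy,
not segmentation quality on real slides.

## Problem sizes and numerical choices

The bundled experiments run at desk scale, chosen so the full two-step
pipeline (extraction, optimization, both brute-force steps under both
validation conditions, aggregation) completes in a few minutes on one CPU:
64x64-pixel samples, 10 images per split, an 18-feature reduced bank
(`reduced_bank_config()`: RGB, HSV, mean/variance at radius 8, LBP at radii
4 and 10, the 5-px Gabor octave), 10 trees, 500 pixels per class per image.
The default pixel cap for full-scale work is 4000 per class per image.
Combination evaluation seeds derive from a 31-bit rolling hash; all seeds
stay below $2^{31}$. Variance computations clamp at zero against rounding;
even-length medians are midpoint averages; all sort orders (combination
tables, tie-breaks, feature names) are bytewise and locale-independent.

## Known limitations

* Exact DV/CV vector agreement is not guaranteed: when several features are
  near-equivalent the final iterations can differ by one member between
  conditions (the original study shows the same single-component
  divergences), which is why `reconcile()` reports its rationale instead of
  failing.
* The brute force is exhaustive within the size limit; no sampling or
  heuristic search is provided.
* The family-scale catalog treats Mean and Var as their own single-member
  families *and* spaces, which slightly inflates the space count used by
  selection rule P2; alternative groupings were not explored.
* Very large window radii are handled by reflective index folding, so
  requesting the 134-px preset radii on images smaller than the window is
  well-defined but of limited statistical meaning; the GLCM bank refuses
  windows larger than twice the image.
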