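---
title: "Geometric self-supervised labeling of retinal lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric self-supervised labeling of retinal lesions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retilab)
```

# The problem

Diabetic retinopathy (DR) produces four prevalent lesion phenotypes on fundus
photographs: microaneurysms (tiny round dark capillary outpouchings),
hemorrhages (larger irregular dark bleeding spots, often vessel-adjacent),
hard exudates (bright lipid deposits with a sharp, monotone intensity
falloff), and soft exudates (bright "cotton-wool" patches with uneven
internal texture).  Training a segmentation network for them normally
requires pixel-level manual annotation, which is slow, expensive, and —
for lesions a few pixels across — unreliable.

`retilab` implements an annotation-free alternative: a geometric stage
labels lesions directly from image structure, and those machine-generated
labels train per-lesion-type U-Net segmentation models.  No human outline
enters the training loop at any point.

# Stage 1: the geometric labeler

## Multiscale contrast shape descriptor

For a pixel with intensity $I(i,j)$ and a ray of length $d$ at angle
$\theta$, define the directional mean contrast

$$ c(\theta) \;=\; \frac{1}{d}\sum_{k=1}^{d} I_k^{\theta} \;-\; I(i,j), $$

where $I_k^\theta$ are intensities sampled at unit arc-length steps along
the ray (bilinear interpolation, border values replicated).  The descriptor
reduces over directions:

* **blob, dark polarity** (bleeding): $\max(0, \min_\theta c(\theta))$ — a
  *consistent positive* contrast in every direction is required, so the
  response survives only where all rays escape into brighter surround;
* **blob, bright polarity** (exudates): $\max(0, -\max_\theta c(\theta))$;
* **linear** (vessels): $\max(0, \max_\theta c(\theta))$ — the
  best-direction signed contrast.  A dark vessel always has a perpendicular
  direction with strongly positive contrast; the halo just outside a dark
  blob does not (its rays into the blob give *negative* contrast), which is
  what keeps the vessel map from ringing around every lesion.

A vessel pixel scores near zero in blob mode because the along-vessel ray
stays inside the vessel ($c \approx 0$), while an isotropic lesion has no
such escape direction.  This single asymmetry is what separates blob-like
lesions from curvilinear structure without any training.

Fields are computed per scale $d \in \{3, 5, 10\}$ pixels (for the
1000×1000 color-fundus profile; 1.5× that for the 1500×1500 ultrawide-field
profile), floored at `contrast_floor` (default 0.04 in normalized intensity
units) to remove noise responses, and merged by pixelwise maximum so each
lesion is represented by the scale that resolves it best while the merged
value remains a contrast magnitude.

**Directions.** `n_directions = 32` by default.  The suppression argument
above needs the sampled direction set to contain a ray that stays inside
the vessel over the *largest* scale: with spacing $\Delta\theta$, a ray
drifts up to $d \sin(\Delta\theta/2)$ off a line.  At 16 directions and
$d = 10$ the worst-case drift is 1.95 px — more than the half-width of a
3-px vessel, so line centerlines leak blob responses above the contrast
floor.  At 32 directions the drift is below 1 px and the leak vanishes;
the acceptance suite measures the disc-to-line response ratio directly.

## Ring-contrast confidence

Candidate regions are the 8-connected components of the positive merged
field (components under `min_area = 2` px are dropped as noise).  Each
region is scored from a signed Euclidean distance field (positive inside,
negative outside; an exact distance transform, equivalent to a
fast-marching signed distance within half a pixel): the maximum interior
distance gives the region radius $r_{\max}$ and its argmax the centroid;
the ring width is $w = \max(1, \mathrm{round}(r_{\max}/4))$.  The *inner
ring* is the interior band of depth $w$ along the boundary, the *outer
ring* the exterior band of width $w$ restricted to the field of view, and

$$ \mathrm{confidence} \;=\; \frac{|\,\overline{I}_{\text{outer}} -
\overline{I}_{\text{inner}}\,|}{\overline{I}_{\text{inner}}} $$

is invariant under multiplicative illumination changes.  Confidence below
0.15 marks a low-confidence region (noise; retained only for bookkeeping),
0.15–0.35 an *indeterminate* region, and ≥ 0.35 a high-confidence region
(threshold boundaries read as "≥ passes").  Dark regions whose outer band
overlaps the vessel map on more than 35% of its pixels are flagged
vessel-fused and removed from the high-confidence set; the published
description words this ratio as the non-vessel share, but only the vessel
share exceeding the threshold is consistent with the rule's stated purpose
of discarding vessel-fused spots, so that is what is implemented.

The interior-band reading of the "inner ring" (rather than a circle of
radius $w$ around the centroid) is forced by the soft/hard exudate rule
below, which needs the ring to partition the lesion into a core and a
shell with one consistent geometry across scoring and typing.

## Rule-based typing

High-confidence regions are typed:

* **Dark regions** — principal component analysis of the boundary
  coordinates gives two eigenvalues; their ratio measures elongation.  A
  region is a *microaneurysm* iff the ratio is ≤ 1.25 **and** its area is
  under 1/200 of the image area; otherwise a *hemorrhage*.  The size rule
  is read as an area fraction, and the two conditions are conjoined,
  because a violation of either contradicts the microaneurysm phenotype
  (tiny and round).  Degenerate (collinear) boundaries get ratio ∞ and
  classify as elongated.
* **Bright regions** — the inner ring splits the lesion into core (signed
  distance > $w$) and shell (the band itself).  The fraction $f$ of shell
  pixels brighter than the core mean is ~0 for a monotone radial falloff
  (hard exudate) and large for speckled cotton-wool texture; $f > 0.15$
  yields *soft exudate*.  Lesions too small to have a core default to hard
  with a warning.

# Stage 2: self-supervised patches and segmentation

## Clean-patch mining

Training windows grow from a high-confidence region's centroid: a 10×10
window expands by 5 px per side while it contains no indeterminate pixel,
capped at 120×120; on the first violation it reverts to the last clean
size, and windows under 60×60 are discarded.  Windows are clipped to the
image bounds and the clipped side counts toward the size tests; the
returned window is squared off inside the clean area.  Only indeterminate
regions block growth — low-confidence pixels are treated as background, as
they fall below the noise cutoff.  For every lesion patch an equal number
of background windows is drawn (seeded rejection sampling, 50 attempts per
patch) from lesion-free images with the same growth procedure, giving
exactly balanced per-type sets.  Per-type datasets are kept separate
because one model is trained per lesion type.

## Segmentation harness

The segmentation model is the classical 4-stage U-Net with 32 encoder
filters doubling per stage (32/64/128/256), implemented natively in R:
3×3 'same' convolutions are im2col gathers followed by BLAS matrix
multiplies, with hand-written backpropagation verified against finite
differences in the test suite.  Training uses the Dice loss, Adam, an
initial learning rate of 0.001 halved when the validation Dice does not
improve for 3 epochs, and early stopping after 10 stale epochs.
Validation is a seeded 10% patch split.  Two implementation choices merit
explanation:

* **Instance normalization** follows every 3×3 convolution.  Without a
  normalization layer the Dice loss has a degenerate attractor: the
  majority-background gradient drives all logits negative, the sigmoid
  saturates, and gradients vanish with the loss pinned at 1 — we observed
  exactly this at the stated learning rate across batch sizes, warmup
  schedules, and activation variants.  Per-sample, per-channel
  standardization removes the failure mode, is independent of batch size,
  and keeps training bit-reproducible.
* **Minibatch-aggregated Dice.**  The loss is computed over the pooled
  pixels of each minibatch rather than per patch, so paired
  background-only patches contribute to the denominator (suppressing false
  positives) instead of forming degenerate empty-target terms whose loss
  is minimized by predicting nothing.

Patches are resampled to a fixed square input side (default 96 px, within
the 60–120 mined range; masks nearest-neighbor).  Inference tiles a full
image with half-window stride, averages overlapping probabilities, and
thresholds at 0.5; connected components of the binary mask are the
detections.  The smoke-scale examples in the tests and the acceptance
script train at input side 32 on 200 patches for 5 epochs, which exercises
the full machinery at desk scale.

# Evaluation

A detection is a true positive iff it shares at least one pixel with any
ground-truth region; a truth region is detected iff at least one detection
overlaps it, and is counted once regardless of multiplicity; detections
overlapping nothing are false positives, reported per image.  No
intersection-over-union threshold is applied (`min_overlap` exposes a
stricter pixel count if wanted).  Size-stratified reports use the
half-open area bins (0,10), [10,50), [50,100), [100,∞) pixels; truth
regions bin by their own area and false positives by the predicted area
(the natural choice, as false positives have no matched truth).

# The synthetic scene generator

Scenes emulate exactly the appearance model the algorithm assumes: a
smooth bright background (mean 0.55) with a low-frequency illumination
field and Gaussian pixel noise (σ = 0.01); dark vessels as spline curves
with Gaussian cross-sections (width 2–5 px, darker by 0.15–0.3, tapering);
microaneurysms as discs of radius 1–3 darker by 0.15–0.35; hemorrhages as
wobbled ellipses (axis ratio 1.5–4, area 50–2000 px sampled log-uniformly,
darker by 0.15–0.35, optionally planted against a vessel and flagged);
hard exudates as discs (radius 3–7) brighter by 0.15–0.4 with a monotone
quadratic falloff; soft exudates as domes (radius 5–10) with ~30% of their
pixels speckled brighter, which places them on the soft side of the 15%
shell rule by construction.  Lesions are pairwise disjoint and — unless
deliberately fused — kept clear of the vessels' full photometric skirt, so
"isolated" means isolated for the scoring rings too.  Contrast priors
deliberately straddle the 0.15/0.35 confidence thresholds so all three
buckets occur.  Identical seeds give bit-identical scenes.

What the generator does *not* model: the optic disc and fovea, drusen and
laser scars, ultrawide-field eyelash/stain artifacts, resolution- and
camera-dependent noise spectra, and the red-channel colorimetry of real
fundus photographs.  Passing tests on these scenes therefore demonstrate
the internal consistency of the geometry — not clinical performance.

# Known limitations

* **Detectable lesion size is capped by the largest scale.**  A flat
  region responds in blob mode only where rays of length $d$ escape it, so
  candidates cover a lesion fully only when its diameter is below roughly
  the largest scale; bigger hemorrhages yield a small interior core whose
  rings sit inside the lesion, giving near-zero confidence.  This is
  intrinsic to the descriptor with scales capped at 10 px.
* **The confidence ratio is asymmetric in polarity.**  Normalizing by the
  inner (lesion-side) mean makes a dark lesion of contrast $\Delta$ on
  background $b$ score $\Delta/(b-\Delta)$ but a bright one only
  $\Delta/(b+\Delta)$: on a 0.55 background, a dark lesion passes the 0.35
  bar from $\Delta \approx 0.13$, a bright one only from
  $\Delta \approx 0.30$ — before accounting for the rim falloff that
  further depresses the inner band of a hard exudate.  Bright-lesion
  recall of the high-confidence bucket is therefore structurally much
  lower than dark-lesion recall under these study conditions; the
  acceptance script reports the measured recovery rate rather than hiding
  the asymmetry.
* Typing operates on the candidate core, whose shape may be rounder than
  the full lesion for large hemorrhages, biasing borderline cases toward
  the microaneurysm label; the size rule usually rescues them.
* The U-Net harness is a desk-scale CPU implementation; it is exact but
  not fast, and full-scale training on thousands of images is out of its
  intended scope.

# Reproducibility

Every stochastic step — scene generation, patch mining, weight
initialization, shuffling, augmentation, validation splits — draws from a
private seeded stream and restores the caller's RNG state.  Rerunning any
pipeline stage with the same inputs, configuration, and seed reproduces
its outputs bit for bit on a fixed BLAS.
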