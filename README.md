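# retilab

Annotation-free geometric detection and labeling of diabetic retinopathy
(DR) lesions on retinal photographs, in R.

Pixel-level ground truth for DR lesions — microaneurysms, hemorrhages,
hard exudates, soft exudates — is the bottleneck of learned segmentation:
outlining one severe image can take hours and tiny lesions are routinely
missed. `retilab` implements a two-stage, self-supervised alternative for
researchers in retinal image analysis. Stage 1 labels lesions from image
geometry alone; Stage 2 uses those machine-made labels to train one U-Net
segmentation model per lesion type, so no manual annotation enters the
training loop.

## The method in brief

**Multiscale contrast shape descriptor.** For pixel intensity $I(i,j)$ and
rays of length $d$ at angles $\theta$, let
$c(\theta) = \tfrac{1}{d}\sum_{k=1}^{d} I_k^{\theta} - I(i,j)$ be the mean
contrast along the ray. Blob-like lesions have a consistent contrast in
*every* direction, vessels have none along their own axis, so

- dark blobs (bleeding): $\max(0,\ \min_\theta c(\theta))$,
- bright blobs (exudates): $\max(0,\ -\max_\theta c(\theta))$,
- curvilinear structures (vessels): $\max(0,\ \max_\theta c(\theta))$,

computed at scales $d \in \{3,5,10\}$ px, floored at a contrast of 0.04,
and merged by pixelwise maximum.

**Ring-contrast confidence.** Each candidate region (8-connected component
of the positive field) is scored from its signed Euclidean distance field:
with ring width $w = \max(1, \mathrm{round}(r_{\max}/4))$, the confidence
is $|\overline{I}_{outer} - \overline{I}_{inner}| / \overline{I}_{inner}$
over the interior/exterior boundary bands. Below 0.15 is noise, 0.15–0.35
*indeterminate*, ≥ 0.35 high-confidence; dark regions whose outer band is
more than 35% vessel pixels are discarded as vessel-fused.

**Rule-based typing.** Dark high-confidence regions are microaneurysms iff
the PCA eigenvalue ratio of their boundary is ≤ 1.25 *and* their area is
under 1/200 of the image area, else hemorrhages. Bright regions are soft
exudates iff more than 15% of their shell pixels exceed the core mean
(cotton-wool texture), else hard exudates.

**Self-supervised patches and U-Net.** Square training windows grow from
each high-confidence region (10×10 start, +5 px steps, 60–120 px final)
while free of indeterminate pixels, paired 1:1 with windows from
lesion-free images, and feed a classical 4-stage U-Net (32/64/128/256
filters, Dice loss, Adam at lr 0.001 with plateau halving and early
stopping) implemented natively in R. Detection quality is scored by
overlap: sensitivity and false positives per image, optionally stratified
by the lesion-area bins (0,10), [10,50), [50,100), [100,∞).

A seeded synthetic fundus generator (background + vessels + all four
lesion phenotypes with per-lesion ground truth) makes every stage testable
without any external data.

## Worked example

```r
library(retilab)

scene <- generate_scene(scene_config(n_microaneurysm = 6), seed = 42)
scene
#> <synthetic_scene> 256x256, 12 lesions, 5 vessels, seed 42

res <- run_geometric_labeler(scene, default_config())
str(res$log)
#> List of 4
#>  $ n_candidates     : int 25
#>  $ n_scored         : int 25
#>  $ buckets          :List of 3
#>   ..$ LOW          : int 4
#>   ..$ INDETERMINATE: int 8
#>   ..$ HIGH         : int 13
#>  $ n_vessel_excluded: int 15

hi <- Filter(function(r) identical(r$bucket, "HIGH") && !isTRUE(r$vessel_excluded),
             res$regions)
table(vapply(hi, function(r) r$lesion_type, character(1)))
#> microaneurysm
#>             6

hi[[1]]
#> <candidate_region #5> area 9 px, polarity DARK, bucket HIGH, confidence 0.981

truth <- scene_truth_regions(scene, "microaneurysm")
pred  <- lapply(hi, function(r) r$idx)
match_and_score(pred, truth, n_images = 1)
#> <detection_report> sensitivity 100.0% (6/6), 0.00 FP/image (0 FP, 1 images)
```

Reading the numbers: the descriptor proposed 25 candidate regions on a
scene containing 12 planted lesions and 5 vessels; ring scoring bucketed
them and the vessel filter removed 15 vessel-fused dark candidates; the 6
surviving high-confidence regions are exactly the 6 planted microaneurysms
(the first has ring confidence 0.981, far above the 0.35 bar), and the
overlap scorer confirms 100% sensitivity with no false positives. Bright
lesions and large hemorrhages rarely reach the high-confidence bucket
under these conditions — a structural property of the confidence ratio
discussed in the methods vignette (`vignettes/geometric-labeling.Rmd`).

For the full chain (mining, smoke-scale training, inference, evaluation):

```r
scenes <- lapply(1:6, function(s) generate_scene(scene_config(side = 320L), seed = s))
out <- run_full_pipeline(scenes, default_config(), seed = 1,
                         types = "microaneurysm", max_epochs = 2, input_side = 32)
```

A thin command-line wrapper ships at
`system.file("cli", "retilab", package = "retilab")` with `synth`, `label`,
and `run-all` verbs.

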