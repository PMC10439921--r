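---
title: "Methods: follicular-cluster detection plumbing and slide-adequacy screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: follicular-cluster detection plumbing and slide-adequacy screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fnascreen` implements the algorithmic layer of a two-stage pipeline for
screening the adequacy of unstained thyroid fine-needle-aspiration (FNA)
slides: patch-based detection plumbing with a pixel-intersection ensemble,
one-pixel-overlap detection evaluation, multi-task loss numerics, and a
hierarchical-bootstrap slide-screening stage with user-threshold sweeps.
This vignette is the package's account of the method: the procedures, their
assumptions, the parameters that matter, the numerical conventions, and the
choices made where the design was genuinely open.

## Coordinate and data conventions

All pixel coordinates are 0-based; bounding boxes are half-open,
`[x_min, x_max) × [y_min, y_max)`, so the box area is exactly
`(x_max − x_min)(y_max − y_min)` and a degenerate box (`x_max ≤ x_min`) is
rejected at construction. Masks are logical matrices indexed
`mask[y + 1, x + 1]`; on disk they are 8-bit PNG with foreground white
(255). A non-binary raster is rejected unless the caller opts into
binarization, which thresholds at ≥ 128 — the midpoint rule matching the
white-on-black labeling convention. Detection sets travel as JSON (bounding
boxes and/or column-major run-length masks, optional scores); the schema is
strict by default because a silently mis-parsed coordinate corrupts counts,
which are the pipeline's whole currency. A lenient mode drops unknown
fields with a warning.

## Tiling and patch labeling

Whole images are covered by square patches (`patch_size` = 256 px) at
stride 128 (50% overlap). Anchors sit at every stride multiple; when the
last multiple falls short of the image edge, one extra anchor is snapped to
`dim − patch_size` per axis. The alternatives — zero-padding the frame or
dropping the remainder — either manufacture synthetic pixels or silently
uncover image area; edge-snapping covers every pixel with real data at the
cost of one locally denser overlap, and on the native 2592 × 1944 frame
yields a 20 × 15 anchor grid.

A patch is labeled follicular when its foreground area **strictly exceeds**
`floor(fraction × patch_size²)` pixels; at the defaults (1%, 256 px) the
cutoff is 655 px, so 656 foreground pixels are positive and 655 are not.
The cutoff is exposed as a fraction so other patch sizes scale it
consistently. Stitching is the union rule — a pixel is foreground iff any
covering patch is positive — which is monotone: relabeling a stitched mask
on the same grid can only grow the footprint, never lose a labeled patch.

Connected components of stitched masks become countable regions.
Connectivity defaults to 8 so that diagonal stitching artifacts merge into
one detection; 4-connectivity is available. The labeler is a small compiled
flood fill whose labels are ordered by each component's top-left pixel in
row-major scan, making region order deterministic. (The labeling is
implemented in the package because the installed image-analysis stack only
exposes a fixed 4-connectivity labeler; that labeler serves as an
independent cross-check in the tests.)

## The intersection ensemble

Two detectors' outputs for an image are rasterized and intersected
pixel-wise; connected components of the intersection (≥ `min_region_pixels`,
default 1) are the ensemble's detections. Intersection — rather than box
IoU matching, score fusion, or non-maximum suppression — is used because
one branch emits stitched mask footprints and the other boxes; rasterizing
both makes the combination representation-agnostic. The operation is
commutative and idempotent, and every ensemble pixel lies in both inputs,
so the ensemble can only shed spurious area: this is the mechanism by which
intersecting a high-precision/low-recall detector with a
high-recall/low-precision one raises precision. A single intersected
component spanning two original boxes counts as one detection; counting
operates uniformly on connected components.

## Detection evaluation

Matching is by one-pixel overlap: a ground-truth cluster with at least one
overlapping prediction contributes one TP; *surplus* predictions
overlapping an already-matched ground truth are ignored — neither TP nor
FP — since the goal is counting clusters, not localizing them. Predictions
touching no ground truth are FP; unmatched ground truths are FN; true
negatives are not counted (they do not enter precision, recall, or F1).
Matching is greedy over ground truths in their deterministic (row-major)
order, each prediction consumable by at most one ground truth — the first
in order that overlaps it. Greedy ground-truth-major assignment keeps both
bookkeeping identities (`tp + fn = |gt|`, `tp + fp + ignored = |pred|`)
invariant under any input, at the cost of not being a maximum matching;
the tests verify it against an independent brute-force oracle on randomized
scenes.

Whole-image IOU divides the intersection of predicted and ground-truth
foreground by their union over the entire image (not per-cluster averages
— the union reading matches the counting purpose). An image with neither
ground truth nor predictions carries no information and is *excluded*
(reported `NA`), not scored 1 or 0; a false-positive-only image scores 0.
The same convention runs through the metrics: a zero denominator makes a
metric *undefined*, surfaced as `NA`, never coerced — and fold aggregation
(mean and sample standard deviation, `n − 1`) drops undefined entries per
metric with the retained count reported.

Model comparison across the 7 folds uses the exact two-sided Wilcoxon
signed-rank test: zero differences dropped, average ranks under ties, and
the null distribution of the positive-rank sum enumerated exactly via a
generating-function convolution (ranks doubled so tied half-ranks stay
integral). Exactness matters at n = 7, where the smallest attainable
two-sided p is 2/2⁷ = 0.015625; a normal approximation would misreport it.
Raw p-values are reported (a Bonferroni option exists, default off).

## Multi-task loss numerics

Four task losses are exposed as pure functions of targets and predictions:
sigmoid focal loss (classification), MAE (cluster-count regression), MSE
(image reconstruction), and BCE (segmentation). Probabilities are clipped
to `[ε, 1 − ε]`, ε = 1e−7, natural logarithms throughout; all losses are
non-negative batch means, zero iff prediction equals target up to ε.

The focal loss has two modes. `literal` evaluates the one-sided form
`−(1/n) Σ β(1−ŷ)^γ log ŷ` over positive-labeled items (β = 0.5, γ = 2 by
default). `two_sided` adds the symmetric negative-class term
`(1−β) ŷ^γ log(1−ŷ)`; on positive-labeled batches, `two_sided` with γ = 0,
β = 1 reduces exactly to BCE. Whether the original training code weighted
negatives is unknowable from the published form, so both modes are
provided and neither is asserted as canonical.

The total loss combines components under trainable per-task log-weights
`α`, initialized to 0 so all tasks start equal. The default (`standard`)
variant contributes `e^{−α} L + α` per task — the homoscedastic-uncertainty
auto-weighting form, whose `+α` regularizer genuinely prevents effective
weights from collapsing: for fixed `L > 0` the optimum satisfies
`e^{−α} = 1/L`. A `literal` variant with `e^{+α} L + α` is retained for
fidelity experiments; its objective is strictly increasing in α with
derivative `e^{α}L + 1 > 0` everywhere, hence unbounded below as
`α → −∞` — a degenerate training objective, which is why it is not the
default (the tests verify both the closed-form minimizer and the
degeneracy). Task ablations freeze a task (no contribution, no
regularizer) or fix a manual weight (e.g. 0.75 on segmentation), with
classification always at weight 1.

## Slide screening

A slide is truly inadequate when its ground-truth cluster count is below
the ground-truth threshold (6 under the standard adequacy criterion; 10 as
a stricter variant), and is *called* inadequate when its predicted count is
below the user threshold. The positive class is the inadequate slide — a
TP is a non-diagnostic slide correctly flagged — because the costly error
is letting a non-diagnostic slide through to staining. Sweeping the user
threshold (default ranges 1–23 for ground-truth threshold 6 and 1–39 for
10, both overridable) traces precision/recall/F1 per threshold; recall is
non-decreasing in the threshold (the flagged set only grows) while
precision typically falls.

PR-AUC integrates trapezoidally over the sweep's (recall, precision)
points: undefined-precision points (no slide flagged) are dropped but kept
in the curve table with their quadrant counts; equal recalls are
deduplicated keeping the maximum precision; the leftmost point's precision
is extended horizontally to recall 0; and no extrapolation is made beyond
the largest attained recall. These anchoring rules are the conservative
standard for PR curves; nothing in the screening definition pins down an
integration rule, so it is fixed here explicitly. The baseline is the
prevalence of truly inadequate slides — the precision of flagging
everything.

The slide-level count is the number of connected detection *regions* by
default. Counting positive *patches* instead is possible through the patch
label maps, but region counting is the default because the ensemble and
the evaluation already operate on regions, keeping the two stages
consistent.

## Hierarchical bootstrap

Test data are multilevel — images within patients — so slides are
simulated by two-level resampling: a group of 6 patients drawn uniformly
with replacement, then 41 images per slide drawn from the group's pooled
images, 10,000 slides in all; a slide's ground-truth and predicted counts
are sums over its images. Design points that were genuinely open:

* **Image draws are with replacement by default.** The source protocol is
  described both ways in different places; with-replacement is the plain
  bootstrap and is the default, with `without_replacement` available (it
  requires the pooled set to be at least the slide size and errors naming
  the shortfall).
* **Pooled-uniform image selection.** Images are drawn uniformly from the
  union of the sampled patients' images, a patient drawn k times
  contributing its images k-fold; a two-stage `patient_then_image` mode
  (patient first, then one of their images) is available. Pooled-uniform
  is the default because it is the direct reading of "sampled from each
  patient group"; the two modes differ when patients have unequal image
  counts.
* **One seeded generator, documented stream order** (group, then slide,
  per iteration), so any slide's provenance is replayable; `run_bootstrap`
  restores the caller's RNG state afterwards.

Because patient-level resampling weights patients equally regardless of
how many images they contributed, a follicular-rich patient who is rare in
the flat image pool is upweighted; the tests assert this rebalancing
qualitatively (hierarchical per-image rate strictly above the pooled rate
on a constructed pool), not any specific ratio, since the real per-patient
composition is unknown.

## The synthetic generator

The generator emulates the *structure* of the study data, not its
appearance: 7 cross-validation groups of 33 background + 8 follicular
images (287 total) attributed round-robin to 6 patients, with elliptical
follicular-cluster blobs (1–3 per follicular image) on Gaussian background
noise (background mean 0.2, blob mean 0.7, sd 0.05 on the unit intensity
scale — a contrast chosen so the reference intensity-threshold detector at
cutoff 0.45 sits 5σ from both classes). Blob areas default to
1,000–30,000 px at the native 2592 × 1944 frame; desk-scale runs use
512 × 512 frames with 800–8,000 px blobs, the proportional equivalent,
and the test suites and acceptance script use that scale throughout (the
native frame is exercised structurally, e.g. the 300-anchor grid, without
rendering full rasters). Fixtures are parametric — blob parameters are
stored and masks/rasters rendered on demand — so the 287-image set never
sits in memory at once.

Two placement rules make detection-level properties of the ensemble
well-posed rather than approximately true:

* blobs are placed with a **minimum 40 px bbox separation**, so each
  cluster is a distinct, unambiguous detection target (no near-touching
  pairs whose detection halos interact);
* simulated spurious boxes keep a **clearance** around ground-truth bboxes
  covering the largest dilation + jitter halo of the detector pair, so a
  simulated false positive is genuinely spurious rather than a halo
  artifact of an over-segmented true detection. Without these rules a
  spurious box clipping the dilation margin of a detected cluster creates
  an intersection component that counts as an ensemble false positive
  while appearing in neither input's FP count — a geometric artifact of
  the simulation, not a property of the method.

Simulated detectors emit each ground-truth region independently with
probability `p_detect` (box dilated by `dilate_px`, translated by at most
`jitter_px`, clipped to the frame), plus Poisson-distributed spurious boxes
with mean `fp_rate` per image — Poisson because spurious detections are
rare independent events, and a stated distribution makes the 3-standard-
error calibration tests well-posed. The paired archetypes are A
(`p_detect` 0.65, `fp_rate` 0.2, dilate 12 — high precision, low recall,
coarse footprints) and B (`p_detect` 0.95, `fp_rate` 2, dilate 1 — high
recall, low precision, tight boxes), the regime in which intersection
helps most. The deterministic intensity-threshold detector exercises the
full tiling path (threshold → patch labels → stitch → components) with no
randomness.

What the generator does **not** emulate: real chromatin texture, stain
variation, irregular cluster morphology, debris and blood, annotation
noise, or the true per-patient composition of follicular images (exposed
as parameters instead). Passing tests therefore validate the counting,
matching, ensemble, bootstrap and screening machinery — not the difficulty
of detecting clusters in real unstained cytology, and not the study's
reported performance numbers, which require the original patients' images
and trained networks.

## Degenerate inputs and numerical conventions, collected

* Empty detection sets, empty masks, and empty folds round-trip and
  aggregate cleanly; an all-background image is excluded from IOU.
* A patch larger than its image is an error (no implicit padding); a
  stride outside `[1, patch_size]` is an error.
* Undefined metrics propagate as `NA` and are dropped-with-count at
  aggregation; an all-`NA` metric aggregates to `NA`.
* The signed-rank test warns and returns p = 1 when every paired
  difference is zero; exact enumeration is capped at 25 non-zero pairs
  (the convolution is exact for any ties).
* Probability clipping ε = 1e−7; focal/BCE gradients and identities are
  tested to 1e−10/1e−6.
* Bootstrap slide sizes, group sizes and counts must be ≥ 1; sampling
  without replacement from a too-small pool errors with the shortfall.

## Problem sizes used by the shipped suites

The test suite and `scripts/acceptance.R` run the full study structure at
desk scale: 287-image fixtures at 512 × 512, 1,000 randomized matching
scenes against the brute-force oracle, 200-image ensemble property checks,
10,000-slide bootstraps, and full threshold sweeps at both ground-truth
thresholds. These sizes were chosen as the smallest that exercise every
structural constant of the study design while keeping the whole suite in
the minutes range on one CPU.

## Known limitations

* The ensemble is plain intersection; score fusion, weighted voting, and
  IoU-based matching of boxes are deliberately out of scope.
* Greedy ground-truth-major matching is order-deterministic but not a
  maximum bipartite matching; with ≤ 6 regions per image the difference is
  immaterial, and the bookkeeping identities always hold.
* PR-AUC depends on the stated anchoring rules at the curve ends; other
  conventions (e.g. interpolated AP) will differ slightly.
* The screening stage consumes counts only; it never revisits pixels, so
  systematic double-counting or merging at the detection stage propagates
  directly into slide classification.
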