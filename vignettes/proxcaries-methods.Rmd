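---
title: "Diagnosing proximal caries on bitewing radiographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing proximal caries on bitewing radiographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxcaries)
```

## The problem

Proximal (interproximal) caries — decay on the surfaces where adjacent teeth
touch — is hard to see clinically and is routinely assessed on bitewing
radiographs, which image the crowns of upper and lower posterior teeth
together. A useful computer-assisted reading has three parts: *detect* each
carious lesion and grade its severity (ICCMS radiographic stages RA =
initial, RB = moderate, RC = extensive), *localize* it to the affected
FDI-numbered tooth, and *name the surface* (mesial = toward the dental
midline, distal = away from it). proxcaries implements the detector-agnostic
parts of that pipeline: annotation interchange, image preprocessing, the
lesion-to-anatomy assignment rules, and the detection-metric protocol, with a
synthetic scene generator so everything is testable without clinical images.

Detection itself (a trained segmentation network) and tooth numbering (a
separate detector) are external components: they enter the pipeline as COCO
annotations with confidence scores and as a sidecar table of FDI-numbered
tooth boxes.

## Coordinates and geometry

All coordinates are continuous pixels, origin at the top-left, x rightward, y
downward. Boxes are stored corner-form `(x_min, y_min, x_max, y_max)` as
closed real intervals; YOLO's normalized center form appears only at file
I/O. Lesions are polygon outlines; a lesion's box is always the polygon's
tight bounds (enforced to 1e-6 px), so box and mask views can never drift
apart.

Mask IoU rasterizes both polygons on the frame's pixel grid with a fixed,
documented fill rule — a pixel belongs to a mask iff its center `(i + 0.5,
j + 0.5)` is inside the polygon under the nonzero winding rule — so mask
IoU values are bit-reproducible. For axis-aligned integer-cornered
rectangles this agrees exactly with box IoU; for fractional corners it
agrees to within a raster pixel or two, which is why the package's tests
compare the two on rectangles.

## Preprocessing

Radiographs are enhanced with contrast-limited adaptive histogram
equalization (CLAHE; clip limit 1.4, 8×8 tile grid by default — a mild
setting that lifts lesion contrast without amplifying noise into false
radiolucencies) and resized to a 1024×768 working scale. The resize scales
the two axes independently (3300×2550 source and 1024×768 target have
different aspect ratios; plain resizing, not letterboxing, keeps coordinate
mapping a pure per-axis multiplication). CLAHE is an image-only step: it
never touches coordinates, so enhancement, resizing and flipping commute in
the obvious way. Dataset augmentation emits each eligible scene three ways
(original, horizontal flip, vertical flip). The test split is never
augmented, so held-out counts are untouched; a horizontal flip also toggles
the recorded bitewing side, because the mirrored image shows the opposite
laterality.

## Assigning lesions to teeth: the three scenarios

Assignment uses bounding boxes only (of the lesion and of the teeth); masks
carry no extra information once the box is tight. For each lesion the
intersecting tooth boxes are found, and exactly one of three scenarios
applies:

1. **One overlapping tooth** — it is the affected tooth.
2. **Several overlapping teeth, unequal overlap** — the tooth with the
   greatest *intersection area* wins. Intersection area, not IoU, measures
   "degree of overlap" here: IoU would penalize large teeth for their size,
   which is irrelevant to where a small lesion sits.
3. **The lesion box completely covered by two (or more) teeth** — possible
   when tooth boxes themselves overlap — or an exact tie in overlap areas:
   the tooth whose nearest *vertical* box edge is horizontally closest to
   the lesion's x-center wins. Proximal surfaces are vertical in bitewing
   orientation, so horizontal distance to a vertical edge is the right
   notion of "closest to the box edge". "Completely covered" is
   operationalized as overlap ≥ (1 − 1e-6) × lesion-box area; exact
   containment would be numerically fragile. Final ties break by ascending
   FDI, keeping the algorithm deterministic.

A lesion overlapping no tooth box is *undetermined* — a value, not an error.
It is the expected outcome at image edges where the tooth-numbering model
detects nothing, and the package reproduces exactly this failure mode when
the generator truncates terminal teeth.

The surface then follows from comparing x-midpoints of the lesion box and
the assigned tooth's box, oriented by the bitewing side. The side fixes
which x-direction is mesial; the package's convention (configurable via
`assignment_config(mesial_positive_side=)`) is that mesial is +x on a right
bitewing and −x on a left one. The underlying anatomy fixes only that the
two sides are mirror images; which display orientation a clinic uses is a
convention, so it is isolated behind a single switch rather than hard-coded.
With it, a horizontal flip of a scene changes neither the assigned tooth nor
the surface of any lesion — a property the test suite checks on generated
scenes. Midpoints that coincide within 1e-9 px, or an unknown and
uninferable side, give an undetermined surface; when the frame side is
unrecorded it is inferred by majority vote over the FDI quadrants of the
detected teeth (quadrants 1/4 ⇒ right, 2/3 ⇒ left).

## Detection metrics

Matching follows the standard detection-evaluation convention: predictions
below the confidence threshold are discarded; within each severity class,
survivors are processed in descending confidence and greedily matched to the
unmatched same-class ground truth of highest IoU, accepted iff IoU ≥ the
threshold. Matching is class-exclusive: a wrong-class overlap is a false
positive for its predicted class and leaves the ground truth unmatched. On
the well-separated geometry the generator produces (pairwise IoUs either
clearly above threshold or zero), greedy matching provably attains the
exhaustive maximum matching; the suite checks this against a brute-force
oracle on small instances.

Precision, recall and F1 use the 0/0 → 0 convention (with a warning) so
empty-prediction edge cases are total. Average precision ranks *all*
predictions (no confidence filter), sweeps the precision-recall curve, makes
the precision envelope monotone non-increasing (all-point interpolation,
isolated so a COCO-style 101-point variant could be swapped in) and
integrates. Counts and rankings are pooled over all images into one
confusion per class — not averaged per image — which is the standard joint
pooling. Macro ("overall") values are unweighted class means; in particular
`mAP = (1/C) Σ AP_c`. The choice matters: the reference overall row that the
acceptance suite reconstructs (precision 0.844, recall 0.864, mAP 0.888, F1
0.851 from the three per-class rows) is reproduced exactly by unweighted
means and not by support-weighted ones. A class with no ground truths has
undefined AP; it is excluded from the macro mean with a warning.

Both box IoU and mask IoU matching are provided (`iou_kind`), since
segmentation and plain detection variants of the task differ in exactly
this; the default is box, and the reference metric protocol does not pin the
choice.

`threshold_sweep()` evaluates the grid {IoU 0.5, 0.75} × {confidence 0.001,
0.25, 0.5} by default — the standard operating-point study — and the suite
asserts the two monotonicities that must hold on any input: recall is
non-increasing in the confidence threshold (fewer predictions survive) and
AP is non-increasing in the IoU threshold (stricter matches).

## The synthetic scene generator

The generator emulates the geometry the assignment algorithm actually
consumes, not radiographic appearance. A 1024×768 frame holds two rows of
four axis-aligned tooth boxes (FDI positions 4–7; upper and lower quadrants
of the chosen side, ordered consistently with the surface convention).
Adjacent teeth are separated by a proximal gap of ~6 px, except that with
probability 0.25 a junction has *overlapping* boxes (8 px deep) — the
configuration that exercises scenario 3. Each tooth surface adjacent to a
junction carries a lesion with probability 0.15 (≈1.9 lesions per scene);
severities are sampled from the clinical class mix RA:RB:RC =
1371:3275:542 ≈ (0.264, 0.631, 0.104). Lesion outlines are diamond-shaped
polygons whose bounds equal the intended box exactly.

Placement is constructed so the ground truth recorded at placement time is
recoverable: gap-junction lesions straddle the owner's edge, either staying
within the gap (scenario 1) or intruding into the neighbour strictly less
than into the owner (scenario 2); overlap-junction lesions sit fully inside
both boxes, offset toward the owner's edge so the nearest-edge rule picks
the owner. This is the desk-scale counterpart of the clinical claim that
fully visible teeth yield perfect tooth/surface identification: on 200
generated scenes with no edge truncation (≈400 lesions), `diagnose_scene()`
recovers 100% of tooth and surface labels, and the acceptance script
recomputes exactly that percentage.

With `edge_truncation > 0`, terminal teeth are dropped from the *detected*
teeth (emulating a tooth-numbering model that misses partially visible teeth
at the film edge) while their lesions and ground truth remain; the resulting
failures are confined to those lesions, qualitatively reproducing the
reported edge-of-image failure mode.

What the generator deliberately does **not** model: anatomical crown
curvature and cervical constriction (assignment consumes boxes, so richer
shapes add nothing testable), overlapping-contact shadows, cervical burnout,
exposure variation, or realistic lesion texture. Its optional rendering
(uniform background, bright tooth rectangles, dark lesion blobs) exists only
so the enhancement and file-I/O paths can be exercised on real rasters.
Passing tests on this generator therefore validate the *algorithmic* claims
— format fidelity, assignment logic, metric arithmetic — and say nothing
about detector accuracy on real radiographs.

The mock detector perturbs ground truth instead of predicting: lesions are
dropped (miss rate 0.12), translated and vertex-jittered (SDs 1.0 and 1.5
px, small relative to lesion size so jittered IoUs stay high), relabelled
through a row-stochastic confusion matrix, and given Gaussian confidences
(true mean 0.85, SD 0.08); spurious detections arrive as a Poisson stream
(rate 0.6 per image, confidence mean 0.30). These rates are fixed, plausible
stand-ins for a decent detector's error profile and exist to give the
threshold-sweep properties non-trivial inputs.

## Numerical and interface choices

* **Determinism.** Every stochastic routine derives its own 32-bit stream
  from a base seed and an index (`(seed·1000003 + index·7919) mod
  2147483629`, exact in doubles) and restores the caller's RNG state, so
  scene `i` is reproducible in isolation and library calls never perturb a
  session's RNG.
* **Ties.** All ordering ties (overlap areas, edge distances, matching
  confidence) break by ascending FDI or stable input order; identical
  inputs always give identical outputs.
* **Splits.** Train/val/test sizes are floor-based with the remainder to
  train (1354 → 1084/135/135 at 80/10/10), after a seeded shuffle.
* **YOLO dialect.** Six decimal places, space-separated, one object per
  line, `<image_id>.txt` per image, empty file for lesion-free images;
  out-of-frame vertices are an error, never silently clipped (clipping
  would break the box/polygon invariant). Round trips preserve labels
  exactly and coordinates to well under 1e-4 normalized units.
* **Degenerate inputs.** Zero-area boxes and sub-3-vertex or zero-area
  polygons are rejected with classed geometry errors; a mask IoU where both
  rasters are empty is an error (undefined), while one empty raster gives 0.
* **Problem sizes.** The test suite and acceptance script run entirely on
  generated data: 200 scenes for the headline assignment rate, 3–12 scenes
  and seeds 0–9 for property sweeps, ≤4×4 instances for the exhaustive
  matching oracle — sizes at which the brute-force oracles are exact and
  the whole suite runs in well under a minute per file.

## Known limitations

* Tooth and lesion geometry is axis-aligned; tilted or rotated dentition is
  out of scope, as are occlusal/buccal/lingual surfaces, multi-surface
  lesions, and primary-teeth notation.
* The mesial-direction convention cannot be validated against anatomy from
  within the package — it is a display convention; deployments must set
  `mesial_positive_side` to match their viewer.
* Macro metrics on sets missing a class are dragged down by the 0/0 → 0
  convention; this is intentional and documented rather than silently
  renormalized.
* The package evaluates detectors; it does not train them, and nothing here
  speaks to how any particular network performs on clinical images.
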