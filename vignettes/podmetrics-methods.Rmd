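---
title: "Coin-calibrated pod morphometry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coin-calibrated pod morphometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podmetrics)
```

## The measurement model

`podmetrics` measures rapeseed (*Brassica napus*) pods photographed on a
dark (black velvet) background together with a reference coin of known
physical diameter placed at the left margin of the scene. Because every
object lies in the same image plane, a single reference object converts
pixel measurements to physical units:

$$
\mathrm{diameter\_ratio} = \frac{\mathrm{coin\_diameter\_true}}{\mathrm{coin\_diameter\_pixel}}
\qquad
\mathrm{area\_ratio} = \frac{\mathrm{coin\_area\_true}}{\mathrm{coin\_area\_pixel}}
$$

with $\mathrm{coin\_area\_true} = \pi\,(\mathrm{coin\_diameter\_true}/2)^2$.
Per-pod traits are derived from the pod's closed contour:

* **length** $= \tfrac{1}{2}\,\mathrm{perimeter}$ — half the closed-contour
  perimeter. This is exact for a degenerate segment and overestimates a
  straight pod of centerline length $L$ and width $w$ by about one width
  (a rectangle yields exactly $L + w$). We keep the estimator as is and
  use the $L + w$ closed form as the test oracle; no curvature or width
  correction is applied.
* **width** $= \mathrm{area} / \mathrm{length}$ — the mean width of an
  elongated shape. The defining sentence of the source protocol
  ("dividing the length by the area") is dimensionally inconsistent
  (it would give 1/length); area over length is the evident intent,
  yields widths in the plausible range for pods measured this way, and
  for a rectangle equals $Lw/(L+w)$ exactly.
* **area** — the shoelace area of the contour polygon, converted by
  `area_ratio`.

The isoperimetric inequality $A \le P^2/(4\pi)$ guarantees
$\mathrm{width} \le \mathrm{length}/\pi$ for every simple closed contour,
so the derived width is always strictly below the derived length; the
test suite asserts this on hundreds of randomized blob contours.

Physical units are millimetres internally; the CSV writer can add cm
columns (`report_cm`), matching how pod tables are usually reported.

## Segmentation pipeline and its tunables

`measure_image()` runs: grayscale (ITU-R BT.601 weights 0.299/0.587/0.114)
→ Gaussian blur → threshold → pixel-area noise removal → contour
extraction → coin identification → calibration → per-pod measurement.

| parameter | default | units | role |
|---|---|---|---|
| `blur_sigma` | 1.5 | px | noise suppression before thresholding; kernel truncated at 4σ, reflect padding |
| `threshold_method` | `"otsu"` | — | between-class-variance maximization over the 256-level histogram; `"fixed"` + `threshold` available |
| `min_component_area` | 150 | px² at 2400×1600 | components smaller than this are background impurities; rescaled by relative image area at other sizes |
| `coin_diameter_mm` | 25 | mm | the reference coin (a one-RMB coin) |
| `circularity_min` | 0.8 | — | coin selector: $4\pi A/P^2$ of a disk is ≈ 1, of an elongated pod ≪ 0.8 |
| `coin_min_area` | 500 | px² | floor preventing small round debris from posing as the coin |

The coin is the leftmost contour passing the circularity and area tests
(the acquisition protocol places it at the far left); exactly one coin is
assumed and its absence is an error that names the best circularity seen.
Its pixel diameter is the mean of the two edge-midpoint distances of its
minimum-area *rotated* bounding rectangle, computed by rotating calipers
over the convex hull — the mean of the two axes is robust to the
rectangle's orientation, and the rotated rectangle (rather than the
axis-aligned one) keeps the estimate orientation-free. Corner ordering
follows the conventional clockwise top-left → top-right → bottom-right →
bottom-left traversal, starting at the corner minimizing $x + y$.

## Boundary convention

Contours are traced as the **0.5-level isoline** of the binary mask
(marching squares on the pixel-center grid, one outer contour per
8-connected component, holes ignored). Vertices sit on pixel-edge
midpoints, half a pixel outside the outermost foreground centers; a
filled $n \times n$ square yields a polygon of area $n^2 - 0.5$, and
every foreground center lies strictly inside the polygon, so
re-rasterizing a contour reproduces its component essentially exactly.
This convention keeps polygon areas in lockstep with pixel counts and
perimeters Euclidean-faithful — both essential, since the calibration
divides a physical area by a contour area and the length estimator is
half a perimeter. It is a fixed geometric convention on the mask, not
intensity-driven sub-pixel edge localization.

Two refinements address known raster biases:

* **Staircase suppression.** On a binary field the isoline of a slanted
  edge is a staircase with cut corners, inflating perimeters by up to
  ~8% near 20° orientations. Contour vertices are therefore smoothed
  with a short circular moving average (window 7) and the smoothed
  polygon rescaled about its centroid to restore the raw enclosed area —
  perimeters of slanted rectangles then come out within ~0.2% while
  areas are untouched.
* **Per-object re-thresholding.** A single global threshold sits at the
  half-intensity of the dominant foreground class. Objects of different
  reflectance (the bright metallic coin among duller pods) get their
  boundary displaced by a fraction of the blur width, and thin pods,
  whose edge-ramp pixels dominate their local histogram, are dilated.
  With automatic thresholding, each component is re-extracted at its own
  half-intensity level — midway between the median background and median
  foreground intensity of its padded bounding box; medians ignore the
  ramp pixels. This removes a 1–4% area bias on narrow pods and keeps
  physical measurements stable across rendering resolutions.

Connectivity is 8-connected foreground over 4-connected background
(component labelling delegates to EBImage's `bwlabel` plus a
diagonal-merge pass). Coordinates are 0-based, x = column, y = row,
origin top-left, pixel centers at integers.

## The synthetic scene generator

No public photographs accompany the protocol, so `render_scene()` /
`random_scene()` emulate the acquisition setup with exact ground truth:
near-black background (intensity 15), a bright coin disk (230) whose
centroid is constrained to the left quarter of the canvas, pods at
intermediate intensity (150), and seeded additive Gaussian noise
(default σ = 5). Pods are constant-width tubes around a centerline —
rectangles, round-capped capsules, or round-capped tubes along a
parabolic arc whose chord is solved so the arc length equals the
requested centerline length (bent pods let tests quantify the
half-perimeter estimator's curvature bias). Trait distributions follow
the ranges reported for dried pods measured this way: centerline lengths
uniform on 4.7–15.1 cm and full widths on 0.2–0.5 cm, orientations
within ±15° of horizontal as pods are laid out lengthwise. Ground truth
(masks, analytic areas, the coin's pixel diameter) is exact by
construction, and rendering is bit-reproducible from the spec.

The default rendering scale is 0.2 mm/px on a 1200×800 canvas (240×160 mm
field of view; the 25 mm coin spans 125 px). The protocol's native
capture resolution is 2400×1600, but its physical sampling is not
documented; 0.2 mm/px keeps objects comfortably above the noise-removal
floor while every test scene renders in under a second. All geometry is
expressed physically, so any `mm_per_px` can be requested — the scale
invariance tests render the same physical scene at 0.2 and 0.1 mm/px and
require physical outputs to agree within 1%.

What the generator does **not** emulate: texture, shadows, specular coin
highlights, uneven illumination, touching or overlapping pods, and the
pod beak/stalk as a distinct structure. Passing tests therefore show the
geometry and calibration machinery is correct under the stated imaging
model, not that segmentation of difficult real photographs is solved.

## Annotations, augmentation and evaluation

Labelme polygon files convert to COCO instances documents
(`read_labelme()` → `to_coco()`): polygons as flat coordinate lists,
`iscrowd = 0`, shoelace areas, tight axis-aligned bboxes, ids assigned
deterministically (images sorted by file name). External detector output
is accepted as COCO results JSON with polygon or RLE segmentations
(both uncompressed counts and the compressed counts string, column-major).

Augmentations (`apply_augmentation()`) cover flips, right-angle and
arbitrary rotation (canvas expanded, nearest-neighbour resampling),
scaling, cropping (polygons clipped by Sutherland–Hodgman; instances
below 20% surviving area are dropped with a message), additive Gaussian
noise, Gaussian blur, cutout, brightness/contrast/saturation jitter, and
2×2 mosaic. Geometric ops transform image and polygons by the same
affine map; photometric ops leave polygons untouched; every stochastic
op is a pure function of (parameters, seed).

Evaluation follows COCO conventions wholesale: greedy score-ordered
one-to-one matching (ties: lower index), AP as the area under the
101-point interpolated precision–recall curve, mAP as the mean over IoU
0.50–0.95 in steps of 0.05, and size strata on ground-truth pixel area
(small < 32², medium 32²–96², large > 96²; out-of-stratum ground truths
are ignore-targets and predictions matched to them, or unmatched with
out-of-stratum area, leave the PR curve). A stratum with no ground truth
reports a missing value, printed as `Nan`. Box-level rows reuse the same
machinery on the masks' filled bounding boxes. Score ties across images
resolve by input order; the tie-break is part of the contract and shared
by the independent brute-force evaluator the tests compare against.

## Numerical choices and degenerate inputs

* Otsu ties resolve to the smallest threshold; binarization is strictly
  `intensity > t`.
* An empty mask yields an empty contour list; a coin-only scene yields an
  empty measurement list (not an error); missing coin is an error.
* `summarize_trait()` computes the mode after rounding (default 1
  decimal), ties to the smallest value; mean/median/min/max use raw
  values.
* Pod ids are assigned left-to-right by contour centroid x (ties by y)
  for deterministic output.
* `mask_iou` defines 0/0 as 0; precision and recall define empty
  denominators as 0.
* Degenerate (collinear) box corners, constant-x regressions, empty
  trait vectors and non-positive calibration inputs raise typed errors.

## Problem sizes used by the checks

The shipped tests and the acceptance script use 1200×800 scenes with 2–5
pods (20 rectangle-recovery scenes, an 18-image determinism batch), one
2400×1600 render for scale invariance, 200 randomized blobs for the
isoperimetric property and 200 toy instance sets (≤ 4 predictions, ≤ 3
ground truths) for exact agreement between the evaluator and brute-force
enumeration — sizes chosen so the whole suite completes in about a
minute and a half while every claim is exercised end to end.

## Known limitations

* The half-perimeter length overestimates straight pods by one width and
  bent pods by $\pi\cdot\mathrm{half\_width}$; strong curvature further
  biases physical length downward relative to the true arc length.
* One coin per image is assumed; multi-coin scenes resolve to the
  leftmost circular object.
* Touching pods merge into one component (the generator never produces
  them; real photographs can).
* Holes, perspective and lens distortion are out of scope; the coin and
  pods are assumed coplanar with the sensor plane parallel.
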