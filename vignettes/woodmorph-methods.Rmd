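---
title: "Measuring macerated wood cells: methods and design notes"
author: "woodmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring macerated wood cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodmorph)
```

## The measurement problem

Wood macerates separate a stem sample into individual cells -- long, thin
fibers (the length phenotype of interest, since hardwood fibers elongate
intrusively at their tips) and shorter, wider water-conducting vessels.
Mounted on a slide and scanned with a motorized brightfield microscope, a
single preparation yields thousands of translucent cells that frequently
overlap. Because the cells are translucent, every cell remains fully
visible even where it crosses another, so an instance-segmentation backend
can (and should) emit a *full* mask per cell rather than a visibility-clipped
one. `woodmorph` takes those per-cell masks or polygon outlines -- from any
backend -- and turns them into calibrated morphometry: length, width, and
area per cell, group summaries, and two-group comparisons.

## Per-cell measurement pipeline

For each cell mask the package computes:

1. **Length.** The mask is thinned to a single-pixel-wide skeleton with the
   Zhang--Suen algorithm, run to fixpoint. The skeleton's *longest path*
   (the pair of skeleton pixels at maximal 8-connected graph distance,
   found by double breadth-first search) is extracted so that side branches
   left by thinning around surface bumps are ignored. Length is reported
   either as the number of pixels on that path (`pixel_count`, the default,
   mirroring the common practice of summing the skeleton image) or as the
   sum of step lengths along it, 1 per axial step and \(\sqrt 2\) per
   diagonal step (`weighted_path`). Pixel counting under-reports diagonal
   runs by up to 29% (a cell at 45 degrees contributes
   \(1/\sqrt2 \approx 0.71\) px of count per px of true length), so
   `weighted_path` is the right choice whenever orientations are arbitrary;
   we keep `pixel_count` as the default because it reproduces the
   conventional skeleton-sum length that slide-scanning pipelines report.
   An `all_pixels` mode (count every skeleton pixel, branches included) is
   provided for comparison with pipelines that skip the longest-path step.
2. **Width.** The exact Euclidean distance transform assigns each
   foreground pixel its distance to the nearest background pixel; the
   maximum sits on the medial axis at the widest point and equals the
   half-thickness, so width is twice the maximum. On a discrete band of
   `w` rows this doubling gives `w + 1` -- a systematic +1 px bias that we
   keep by default (it is the conventional definition) and remove with
   `bias_correction = TRUE` (`2*max - 1`).
3. **Area.** The shoelace area of the source polygon when one exists
   (matching contour-area conventions); the foreground pixel count for
   mask-only input. Both conventions are exposed because they differ by
   roughly half the perimeter.
4. **Calibration.** Pixel measures convert to micrometers with a scalar
   `um_per_px` (default 0.65, a 10x objective with a 0.70x C-mount);
   lengths and widths scale linearly, areas quadratically. The identity
   `length_um / length_px == um_per_px` is exact by construction.
5. **Border exclusion.** A cell whose mask (or outline) touches the image
   border is partially cut off, so its measurements are biased low. Such
   records are flagged and, by default, excluded from summaries -- but
   always written to the per-instance table, so nothing is silently
   dropped. The test is evaluated against the *full stitched* image frame,
   never a tile frame; the `margin` parameter (default 0 = strict touch)
   widens the guard band.

### Numerical choices

* The distance transform is the exact Euclidean transform (Felzenszwalb's
  two-pass parabola method over squared distances), not a chamfer
  approximation, so it can be verified pixel-for-pixel against a
  brute-force nearest-background search -- the test suite does exactly
  that on masks up to 64x64. The mask is padded by one background pixel
  before the transform so cells touching the crop edge still get finite
  distances.
* The double-BFS longest path is exact on acyclic skeletons. Skeletons
  with cycles (vessels whose perforation plates survive thinning as loops)
  make it a heuristic; an exhaustive all-pairs mode (`exact = TRUE`)
  is available and is what the tests compare against, via an independent
  graph-library oracle. Ties in farthest-pixel selection are broken
  lexicographically by (row, col) and the returned path is oriented from
  its lexicographically smaller endpoint, so results are reproducible.
* Pixel (r, c) has its center at continuous (x = c, y = r), 0-based.
  Polygon rasterization marks a pixel foreground iff its center is inside
  by the even-odd rule *or exactly on the boundary* (a deterministic
  tie-break); self-intersections resolve by the even-odd rule, consistent
  with the absolute shoelace area.
* An axis-aligned corner in a skeleton is traversed diagonally by the
  longest path: under 8-connectivity, an L of 5 + 5 pixels yields an
  8-pixel path (6 axial + 1 diagonal step), not 9. This is a property of
  the 8-connected graph metric, not a defect; the `all_pixels` mode counts
  all 9.

## The synthetic scene generator

No trained segmentation network ships with this package, so validation
rests on a seeded generator of synthetic macerate scenes with exact ground
truth. Each cell is a *stadium*: a disk of diameter `w` swept along a
quadratic Bezier centerline, giving closed forms for the truth values --
centerline arc length `L`, width `w`, and area `L*w + pi*(w/2)^2`. The
mask is rasterized by exact point-to-segment distance, and the outline
polygon is the analytic offset contour (centerline offset by `w/2` on both
sides plus semicircular end caps), whose shoelace area matches the closed
form to well under 1%.

Defaults emulate one 1920 x 1440 field of view at 0.65 um/px: fiber
lengths log-normal with mean 460 px (about 300 um) and sd 120 px, widths
normal (truncated at 3 px) with mean 35 px (about 23 um) and sd 5; vessels
log-normal 380 +/- 80 px long and normal 78 +/- 8 px wide; centerline bow
up to 15% of length; six fibers and one vessel per field. These are
scaled from typical published aspen macerate averages at this calibration
and are *fixed study conditions*, not tuning knobs. The image composite
follows Beer--Lambert stacking: brightfield background at 0.92 of full
scale, each covering cell multiplying transmitted light by
`exp(-absorbance)` per channel with a class-specific stain tint (fibers
redder, emulating safranin), plus per-pixel Gaussian noise. Overlapping
regions are therefore darker than single-cell regions, and -- the property
the whole pipeline depends on -- each instance's stored mask is computed
from its own geometry alone, so overlap *never* clips ground truth.

What the generator deliberately does not model: cell-wall texture and
lumen, tapering ends (real fibers are spindle-shaped, stadiums are
constant-width), optics (no point-spread function), or stain chemistry.
Passing the parameter-recovery tests therefore demonstrates that the
measurement chain is unbiased on known constant-width geometry; it does
not certify accuracy on tapered real cells, where "width" itself is
ambiguous.

Scenes are byte-identical for identical (spec, seed): instance sampling
and noise draw from one seeded RNG stream. `render_image = FALSE` skips
image compositing (ground truth and masks are unchanged) and is used for
the larger statistical harnesses.

## Evaluation metrics

Matching is greedy in descending confidence (ties broken by instance id):
each prediction takes the unmatched same-class ground truth of highest
mask IoU at or above the threshold. Ground truths that overlap each other
are each independently matchable -- the translucent-overlap case is the
point of the exercise. AP uses COCO-style 101-point interpolation of the
precision envelope (a continuous VOC-style integral is available by flag);
mAP@0.5 averages per-class AP at IoU 0.5 and mAP@0.5:0.95 averages over
thresholds 0.50 to 0.95 in steps of 0.05. True negatives are undefined
for instance detection and are not reported. Multi-image evaluation pools
TP/FP/FN across images for precision/recall/F1 and pools the ranked
prediction list per class for AP. By convention, precision is 1 when
nothing was predicted and recall is 1 when there was nothing to find.

## Group statistics

Two groups are compared with the two-independent-samples t statistic
\(t = (\bar X_1 - \bar X_2)/\mathrm{SED}\). The default pools variances
(Student), matching the default of the common two-sample routine; Welch
(`equal_var = FALSE`) is exposed and recommended for unequal group sizes.
p-values are two-sided by default. Box-plot style summaries use
linear-interpolation quantiles (type 7), the common plotting default.
Percent change is reported relative to the first (reference) group. The
suite checks type-I calibration empirically (2,000 null pairs at n = 50
must reject at 3.5--6.5% for alpha = 0.05) and power (a planted 12%
length difference at n = 500/group is detected at p < 1e-4 in at least
19/20 seeded repetitions).

## Tiling and cross-tile merging

Slide scans of tens of thousands of pixels per side are processed in
1024-px tiles with 10% overlap -- tiling, not resizing, so the um/px
calibration is preserved. Detections from overlapping tiles are merged:
same-class pairs with mask IoU >= 0.8 collapse to the higher-confidence
copy (distinct overlapping cells rarely exceed 0.5 IoU; duplicate
detections of one cell exceed 0.9), and a cell touching an interior tile
edge is trusted only if some copy of it is complete in another tile,
otherwise it is flagged `fragmented` and excluded from summaries. For
interior cells the tiled path reproduces whole-image measurement records
exactly, which the tests assert record-for-record.

## Problem sizes used in the validation suite

The shipped tests validate at sizes chosen to exercise every code path
while staying comfortable on a laptop: oracle comparisons on masks up to
64x64; parameter recovery on 200 fibers plus 200 vessels across ten
2560 x 1920 scenes (mean length within 5% of the realized ground-truth
mean, mean width within 2 px); scale invariance on 20 seeded pairs of
disjoint 100-fiber fields (group means must be indistinguishable at
p > 0.05 in at least 18 of 20); calibration on 2,000 null pairs. The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
from scratch under a caller-supplied seed.

## Known limitations

* `pixel_count` length is orientation-biased by construction; use
  `weighted_path` for arbitrary orientations.
* Width is the *maximum* inscribed-disk diameter -- one number per cell.
  Tapered or locally swollen cells are not profiled along the axis.
* The longest-path heuristic may shorten measured length on skeletons with
  large loops; `exact = TRUE` exists but is quadratic.
* Greedy matching is the COCO convention, not an optimal assignment;
  pathological confidence orderings can cost a match that the Hungarian
  algorithm would find.
* The generator's stadium geometry has no taper, texture or optics; see
  above for what recovery tests do and do not establish.
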