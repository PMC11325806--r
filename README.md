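# woodmorph

Morphometry of macerated wood fibers and vessels from instance-segmentation
output.

Macerating a wood sample (soaking it until the middle lamella dissolves)
separates the stem into individual cells: long, thin **fibers** -- whose
length is a key wood-quality phenotype, since hardwood fibers elongate
intrusively at their tips -- and shorter, wider **vessels**. Spread on a
slide and scanned with a brightfield microscope, one preparation yields
thousands of translucent cells that overlap freely while remaining fully
visible. Modern instance-segmentation backends can emit a *full* mask per
cell despite the overlaps; `woodmorph` is everything that comes after the
backend: it turns per-cell masks or polygon outlines into calibrated
measurements, evaluates segmentation quality, and runs the group
comparisons a tree-biology experiment needs. It is aimed at plant
scientists quantifying fiber/vessel morphology at scale and at developers
validating segmentation backends for this kind of imagery.

## What it computes

Per cell, from its binary mask (micrometer scale via `um_per_px`, default
0.65):

* **length** -- Zhang–Suen thinning to a single-pixel skeleton, longest
  skeleton path by double BFS, then either the path pixel count or the
  step-weighted path length (1 per axial, √2 per diagonal step):
  `L = Σ w(step)`;
* **width** -- twice the maximum of the exact Euclidean distance transform,
  `W = 2 · max_p dist(p, background)`, the diameter of the largest
  inscribed disk;
* **area** -- shoelace area of the source polygon, or the foreground pixel
  count for mask-only input;
* **border flag** -- cells touching the image border are flagged and
  excluded from summaries (they are partially cut off and bias lengths
  low).

Around that core: readers/writers for VGG Image Annotator JSON, YOLO
segmentation labels and per-instance mask PNGs; tiling of large scans with
cross-tile deduplication; COCO-style evaluation (greedy confidence-ordered
matching on mask IoU, precision/recall/F1 = 2PR/(P+R), per-class AP with
101-point interpolation, mAP@0.5 and mAP@0.5:0.95); pooled and Welch
two-sample t tests, t = (X̄₁ − X̄₂)/SED, with percent-change reporting; and
a seeded synthetic-macerate generator whose stadium-shaped cells carry
exact ground truth (length L, width w, area L·w + π(w/2)²) for end-to-end
validation without any trained network.

## Worked example

Simulate a field of view, measure every cell, and score a perfect
segmentation of it:

```r
library(woodmorph)

spec  <- scene_spec(width_px = 1024L, height_px = 768L,
                    n_fibers = 5L, n_vessels = 1L, seed = 4L)
scene <- render_scene(spec)
masks <- lapply(scene$instances, `[[`, "mask")

records <- measure_collection(masks, calibration(0.65),
                              image_width = 1024L, image_height = 768L,
                              image_id = "demo",
                              length_mode = "weighted_path")
records[, c("instance_id", "class", "length_um", "width_um", "area_um2")]
#>   instance_id  class length_um width_um area_um2
#> 1     syn_001  fiber     311.5    22.10     6776
#> 2     syn_002  fiber     465.5    25.24    11486
#> 3     syn_003  fiber     473.5    28.72    14065
#> 4     syn_004  fiber     332.3    22.70     7616
#> 5     syn_005  fiber     392.8    23.00     9216
#> 6     syn_006 vessel     337.8    51.80    19262

summarize_records(records, "length_um", "demo")
#>   group_id     field n  mean    sd median    q1    q3   min   max
#> 1     demo length_um 6 385.6 70.38  365.3 333.7 447.3 311.5 473.5

preds <- lapply(masks, function(m) { m$confidence <- 0.9; m })
map_metrics(preds, masks)
#> <ap_summary: mAP@0.5 = 1.000, mAP@0.5:0.95 = 1.000, best F1 = 1.000 at conf 0.00>
```

The measured fiber lengths sit within a few percent of the generator's
ground-truth centerline lengths (305.9, 440.2, 470.7, 319.2, 390.1 µm for
the five fibers above); widths land within about 1 px of truth. The
`excluded` column (all `FALSE` here) marks border-touching cells.

A command-line wrapper ships in `inst/cli/woodmorph` with subcommands
`simulate`, `convert`, `measure`, `evaluate` and `compare`.

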