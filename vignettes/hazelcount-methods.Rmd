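---
title: "Counting hazelnut female flowers by tiled detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting hazelnut female flowers by tiled detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazelcount)
```

## The measurement problem

Hazel is monoecious and diclinous: male catkins are large and conspicuous,
but the female flowers (glomerules) that determine yield are bud-like and
marked only by millimeter-scale red pistils. In a photograph framing the
whole plant, a flower spans ~17–20 px even at 45 MP, and its reds blend
into the brown of winter branches. A detector applied to the full frame
would see each object at a few thousandths of the image width; the pipeline
therefore decomposes each image into square tiles, detects per tile, sums
the detections, and corrects the systematic counting bias by regression
against manual reference counts.

This package implements everything around the detector — geometry,
annotation, metrics, counting, calibration — plus a synthetic data module
that substitutes for the trained network and the (unavailable) field
imagery. The network itself is deliberately out of scope: detectors enter
through a functional contract.

## Tiling geometry

Coordinates are 0-based and boxes half-open (`[x_min, x_max)`), so areas
and intersections are exact and tiles partition the padded image: every
pixel belongs to exactly one tile, and `assemble_tiles()` inverts
`split_into_tiles()` bit for bit. For an image of `W × H` px and tile size
`t`, `n_cols = ceiling(W/t)`, `n_rows = ceiling(H/t)`; black (zero)
padding is applied to the right and bottom edges only, keeping the origin
fixed so original pixels keep their coordinates.

```{r}
plan_tile_grid(8256, 5504, 400)
```

**Tile size (400 px, default).** With flower diameters of 17–20 px, a
400 px tile gives each object a ~5% linear footprint with enough context
to discriminate flowers from buds. **Objects crossing tile borders** are
clipped per tile — fragments are kept (`clip_box_to_tile()`), never merged
across tiles, mirroring the independent-tile processing of the field
pipeline. The possible double count at borders is documented, not
corrected here; the downstream calibration absorbs it.

## Annotation

Manual annotation yields binary masks (1 = flower pixel).
`mask_to_boxes()` encloses each connected foreground component in its
minimal axis-aligned rectangle and normalizes by the mask size, class 0.
Design choices:

* **8-connectivity** (a compiled two-pass union-find): tiny blobs often
  connect diagonally, and 4-connectivity would split them.
* **No minimum-area filter by default** (`min_area = 0`); fragments created
  purely by tile clipping are legitimate objects under independent-tile
  processing.
* **Label precision fixed at 6 decimals**, making
  `read_labels(write_labels(x))` the identity and files byte-stable.

`build_dataset()` reproduces the balanced-dataset construction: tile all
image/mask pairs, label each tile, then draw `target_size` tiles of which
`round(empty_fraction × target_size)` contain no objects (default 30%
empty, matching the published training set of 2000 tiles), deterministic
given the seed, with an explicit shortfall error when a class of tiles
runs out.

## Detection metrics

`IoU(A, B) = |A ∩ B| / |A ∪ B|`. A prediction is a true positive when its
IoU with an unmatched ground truth reaches the threshold. Choices the
defining equations leave open were fixed to the de-facto benchmark
conventions, and are all deterministic:

* **Matching protocol**: greedy in descending confidence; each prediction
  takes the unmatched ground truth of highest IoU; IoU ties break toward
  the lower ground-truth index; confidence ties break by input order
  (stable sort). On instances where each prediction overlaps at most one
  ground truth above threshold, this equals exhaustive assignment search
  (property-tested against a brute-force enumerator over 1000 random
  instances).
* **AP interpolation**: all-point precision envelope
  `P(R) = max{precision at recall ≥ R}` over observed recall levels, with
  `AP = Σ P(R_k) ΔR_k`. The sweep over confidence cutoffs is computed
  cumulatively, which is exact because greedy matching is itself
  confidence-ordered.
* **Degenerate conventions**: precision of zero predictions and recall of
  zero ground truths are 1.0; `average_precision()` with no ground truth
  anywhere is an explicit error; mAP of zero predictions is 0.
* **mAP@50-95** averages AP over thresholds `seq(50, 95, 5)/100` —
  constructed as exact hundredths so a box engineered to have IoU exactly
  0.70 compares equal at the 0.70 rung.

## Counting and the detector contract

`detect_tiles()` pads, tiles, applies the detector per tile, drops
detections with confidence below the cutoff (default **0.5**, the field
setting that suppresses false positives such as buds and branch nodes) and
maps survivors to global coordinates. The detector is a contract:

```
function(tile_image, row, col) -> data.frame(x_min, y_min, x_max, y_max, confidence)
```

in tile-local pixels, confidences in [0, 1]. Violations abort with the
offending tile named. The contract passes the tile indices — a deliberate
widening relative to a pure tile-raster callable — because the oracle
detector must know *which* tile it is shown to replay ground truth
deterministically and independently of processing order; a trained-model
adapter simply ignores the two extra arguments.

Per-side counts are sums over tiles; a plant's raw total is `side a +
side b` with **no cross-side deduplication and no cross-tile NMS** — both
simplifications are accepted by design and handed to the calibration.

## Calibration

`fit_ols()` fits `reference = a·raw + b` by ordinary least squares with
95% t-intervals (`n − 2` df); it refuses `n < 3` or constant raw counts.
`apply_calibration()` floors corrected counts at zero and reports reals
(reference counts are operator averages with decimals); rounding is a
display option. Because the published field calibration was fitted on an
unspecified subset of the seven plants — full-data OLS on the packaged
table gives slope 2.31, not the published 1.980 — `calibrate_counts()`
exposes three documented modes (`full`, `loo`, `subset`) and treats the
published equation as display-only.

`error_metrics()` fixes two conventions that reproduce the published
figures from the published table: the APE dispersion uses the
**population** (divisor-n) standard deviation (the sample formula gives
5.67% where 5.25% was printed), and R² is `1 − SS_res/SS_tot` against the
reference (not a squared correlation), which penalizes bias and reproduces
0.989.

```{r}
fc <- field_counts()
error_metrics(fc$plants$raw_total, fc$plants$reference)
error_metrics(fc$plants$corrected, fc$plants$reference)
```

## The synthetic world

The generator emulates the *statistics that the pipeline is sensitive to*,
not photorealism:

* **Flower areas**: a mixture with 83% of mass uniform on [280, 320] px²
  and 17% split over [150, 280) ∪ (320, 500] px² proportionally to the two
  tails' widths — matching the published area histogram's summary without
  inventing its exact shape. Rasterization is rank-based (the `A` pixels
  closest to the center in the ellipse metric), so pixel areas match the
  sampled areas exactly and the 83% check is a clean binomial.
* **Placement**: centroids uniform over the allowed region, rejection-
  sampled; flowers keep a 2 px clearance (so mask components = flower
  count by construction) and, by default, avoid tile borders so that
  conservation properties are exact. A bounded retry count turns an
  overcrowded request into an explicit placement error.
* **Background**: brown-gray base with Gaussian pixel noise and dark
  branch-like strokes; flowers are reddish ellipses. Only size, placement
  and contrast statistics matter to the test surface.
* **Scene size default 1600 × 1200** (a 4 × 3 tile grid) with **15
  flowers**: the field label density was ~1.3 flowers per tile with ~30%
  of tiles empty, and 15 uniform flowers over 12 tiles reproduce both to
  first order. Scene size is a test-surface choice, not a stated property
  of the measurement system; the reference 8256 × 5504 frame is exercised
  where only arithmetic is needed.

The **oracle detector** replays ground truth with controllable failure
modes: per-flower miss probability, Poisson false positives per tile with
low Beta-distributed confidences (default `Beta(2, 5)`, mostly under the
0.5 cutoff, as real misdetections score low), Gaussian center jitter
clamped to the tile, and an optional Beta confidence model for true
detections (default: constant 1, so the zero-noise oracle is exactly
perfect). Each tile's randomness is seeded from `(seed, row, col)`:
results are reproducible and independent of tile order.

**Plant scenarios** (`plant_scenario()`) model the two-side count: each
flower faces one side, is visible on its facing side with probability
`v = 0.48`, visible from the opposite side with probability `d = 0.04`
(double counts), detected with probability `1 − m`, `m = 0.05`, plus one
false positive per side. These defaults were chosen once so the implied
correction slope `1/((v + d)(1 − m)) ≈ 2.02` matches the ≈2× undercount
observed in the field, and were not revisited. True counts are uniform on
150–650, the span of the field reference counts. In the alternative
`bias` mode the reference is generated from the raw total through a known
line plus Gaussian noise (σ = 5 flowers) rounded to quarters — averages of
four integer operator counts are quarter-integers — which is the
textbook regression setting used for coverage testing of `fit_ols()`.

What a green test does **not** establish: the synthetic scenes contain no
occlusion by branches, no lighting or focus variation, no catkins or buds
(the real confusers), and the oracle's errors are independent across
flowers and tiles. Greens certify the *pipeline arithmetic* —
tiling, labeling, matching, aggregation, calibration — not detector
quality on real canopies.

## Numerical choices and degenerate inputs

* IoU thresholds are built as integer hundredths; no epsilon fudges
  anywhere in metric comparisons.
* Exact linear calibration data yields zero-width confidence intervals
  (reported explicitly rather than `lm`'s NaN).
* Empty masks, empty label files, zero-flower scenes, zero-prediction and
  zero-ground-truth evaluations all have defined, tested behavior.
* All randomness flows from explicit seeds through scoped RNG state; no
  function disturbs the caller's `.Random.seed`.

## Known limitations

* No cross-tile NMS: an object straddling a tile border can be counted
  once per tile. Faithful to the reference pipeline; measurable with
  `avoid_tile_borders = FALSE`.
* The calibration is as transferable as its reference counts — fitted
  under specific acquisition conditions, it should be refitted per
  orchard/cultivar.
* The published regression equation cannot be reproduced from the
  published table (unknown fitting subset); the package reports what the
  chosen mode actually computes.
* `mAP@50-95 = 0.89` of the trained network is not reproducible without
  the network and dataset; the metrics module is validated against
  oracles and hand-computed cases instead.
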