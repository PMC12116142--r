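# hazelcount

Counting the female flowers of hazel (*Corylus avellana*) is the earliest
reliable predictor of a plant's annual nut yield — and one of the most
tedious field measurements in orchard phenotyping. The flower (a
*glomerule*) is a bud-like structure distinguishable only by red pistils a
few millimeters long: in a whole-plant photograph it spans roughly 17–20
pixels even on a 45 MP sensor. Manual counting takes 30–60 minutes per
plant with large inter-operator variability.

`hazelcount` implements the image-analysis pipeline that makes automated
counting of such small, low-contrast objects practical, for agronomists and
computer-vision practitioners alike:

1. **Tiling** — each high-resolution side image is padded and partitioned
   into square 400 px tiles (a reference 8256 × 5504 frame gives
   21 × 14 = 294 tiles), so flowers occupy a usable fraction of each frame
   processed by a detector.
2. **Annotation** — binary masks from manual segmentation are converted to
   minimal enclosing rectangles per 8-connected component and written in
   the standard normalized detection-label format
   (`class x_c y_c w h`, one object per line).
3. **Evaluation** — IoU, greedy confidence-ordered matching, precision
   `TP/(TP+FP)`, recall `TP/(TP+FN)`, all-point interpolated average
   precision `AP = Σ_k P(R_k) ΔR_k`, and `mAP@50-95`, the mean of AP over
   IoU thresholds 0.50, 0.55, …, 0.95.
4. **Counting** — a pluggable detector (any
   `function(tile, row, col) → boxes + confidence`) is run per tile;
   detections with confidence < 0.5 are discarded; per-side counts are
   summed over tiles and the two opposite sides of a plant are added.
5. **Calibration** — raw totals systematically undercount (occlusion,
   out-of-frame flowers) and occasionally double count (flowers visible
   from both sides). An OLS line `y = a·x + b` fitted against manual
   reference counts corrects the bias; accuracy is reported as MAE, MAPE,
   the population standard deviation of absolute percentage errors, and
   `R² = 1 − SS_res/SS_tot`.
6. **Synthesis** — a scene generator (elliptical reddish blobs with ~83%
   of pixel areas in 280–320 px² over branch-textured background, uniform
   centroids, non-overlapping) and a noise-configurable oracle detector
   make every stage testable with no trained network and no field data.

Training the neural detector itself is out of scope; the detector is a
contract, and the shipped oracle satisfies it from ground truth.

## Worked example

Tiling arithmetic of the reference camera frame:

```r
library(hazelcount)
plan_tile_grid(8256, 5504, 400)
#> tile grid: 8256 x 5504 px, tile 400 px -> 21 cols x 14 rows = 294 tiles (pad right 144, bottom 96)
```

A synthetic side image, counted by the zero-noise oracle — exact
conservation of the 20 planted flowers:

```r
sc   <- generate_scene(scene_spec(n_flowers = 20, seed = 3))
det  <- make_oracle_detector(sc$boxes, 1600, 1200)
count_side(det, sc$image, plant_id = 1, side = "a")
#> plant 1 side a: 20 flowers detected
```

The packaged seven-plant field table (per-side detector counts, manual
reference counts and published corrected totals) reproduces the published
accuracy figures exactly:

```r
fc <- field_counts()
error_metrics(fc$plants$raw_total, fc$plants$reference)
#> n = 7 plants: MAE = 141.75 flowers, MAPE = 37.29% (APE sd 11.88%), R^2 = -0.094
error_metrics(fc$plants$corrected, fc$plants$reference)
#> n = 7 plants: MAE = 15.81 flowers, MAPE = 6.54% (APE sd 5.25%), R^2 = 0.989
```

The raw pipeline underestimates by a third (MAPE 37.29%); after the linear
bias correction the error is comparable to inter-operator variability of
manual counting (MAPE 6.54%). Calibration recovery on simulated plants:

```r
tab <- simulate_plant_counts(plant_scenario(seed = 9), 20)
fit_ols(tab$raw_total, tab$reference)
#> count calibration: y = 2.101 x + -12.473  (n = 20)
#>   95% CI slope [1.976, 2.225], intercept [-35.742, 10.797]
```

The default scenario's implied correction slope is
`scenario_implied_bias(plant_scenario())$slope` ≈ 2.02, inside the fitted
CI.

## Command line

```sh
inst/cli/hazelcount tile      --image plant.png --out tiles/ --tile-size 400
inst/cli/hazelcount labels    --mask mask.png --out labels/ --per-tile
inst/cli/hazelcount evaluate  --pred-labels preds/ --gt-labels labels/ --image-size 400x400
inst/cli/hazelcount count     --backend oracle --image-a a.png --labels-a a.txt \
                              --image-b b.png --labels-b b.txt --slope 1.98 --intercept 13.311
inst/cli/hazelcount calibrate --counts counts.csv --mode full --out report.json
inst/cli/hazelcount simulate  --what counts --n-plants 7 --seed 1 --out counts.csv
```

`--config file.yaml` supplies defaults for any flag; explicit flags win.

## Vignette

`vignettes/hazelcount-methods.Rmd` documents the model and its assumptions,
all tunable parameters with their defaults and rationale, what the
synthetic generator does and does not emulate, and known limitations.
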