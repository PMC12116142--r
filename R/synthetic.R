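#' Specify a synthetic flowering-canopy scene
#'
#' The generator emulates the statistical properties of annotated field
#' imagery that matter to the counting pipeline, not photorealism: flower
#' blobs whose pixel areas put 83% of their mass in 280-320 px^2 (roughly
#' 17-20 px across), centroids uniformly distributed over the allowed
#' region, and a brown/gray branch-textured background against which the
#' reddish blobs are low-contrast. Flowers never overlap each other (2 px
#' clearance) so the mask's connected components equal the flower count by
#' construction.
#'
#' @param width,height scene size in pixels. The default 1600 x 1200 is a
#'   4 x 3 grid of 400-px tiles: large enough to exercise tiling, small
#'   enough for fast tests (the field reference frame is 8256 x 5504).
#' @param n_flowers number of flowers to place. The default 15 matches the
#'   sparse field density (~1.3 flowers per tile, leaving roughly 30% of
#'   tiles empty under uniform placement).
#' @param area_core,core_mass pixel-area interval holding `core_mass` of the
#'   flower-area distribution (defaults `[280, 320]` px^2 and 0.83).
#' @param area_tail support of the remaining mass, split uniformly below
#'   and above the core (default `[150, 500]` px^2).
#' @param aspect_range flower ellipse aspect-ratio range (default 0.7-1.4).
#' @param tile_size tile side used for border avoidance (default 400).
#' @param avoid_tile_borders keep each flower inside a single tile (default
#'   `TRUE`; set `FALSE` to allow border-straddling objects).
#' @param margin minimum clearance from the image border, px.
#' @param render render an RGB image (`TRUE`, default) or return `NULL` for
#'   the image slot (mask and boxes only; faster for huge scenes).
#' @param seed integer seed; scenes are deterministic given the seed.
#' @return list with class `scene_spec`.
#' @export
scene_spec <- function(width = 1600L, height = 1200L, n_flowers = 15L,
                       area_core = c(280, 320), core_mass = 0.83,
                       area_tail = c(150, 500), aspect_range = c(0.7, 1.4),
                       tile_size = 400L, avoid_tile_borders = TRUE,
                       margin = 2L, render = TRUE, seed = 1L) {
  stopifnot(width > 0, height > 0, n_flowers >= 0,
            area_core[1] > 0, area_core[2] > area_core[1],
            core_mass >= 0, core_mass <= 1,
            area_tail[1] > 0, area_tail[2] > area_core[2],
            area_tail[1] < area_core[1])
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_flowers = as.integer(n_flowers), area_core = area_core,
                 core_mass = core_mass, area_tail = area_tail,
                 aspect_range = aspect_range, tile_size = as.integer(tile_size),
                 avoid_tile_borders = isTRUE(avoid_tile_borders),
                 margin = as.integer(margin), render = isTRUE(render),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# area mixture: core_mass uniform on the core interval, the rest split
# between the low and high tails proportionally to their widths
sample_flower_areas <- function(n, spec) {
  lo_w <- spec$area_core[1] - spec$area_tail[1]
  hi_w <- spec$area_tail[2] - spec$area_core[2]
  u <- stats::runif(n)
  a <- numeric(n)
  core <- u < spec$core_mass
  a[core] <- stats::runif(sum(core), spec$area_core[1], spec$area_core[2])
  tl <- !core & (stats::runif(n) < lo_w / (lo_w + hi_w))
  a[tl] <- stats::runif(sum(tl), spec$area_tail[1], spec$area_core[1])
  rest <- !core & !tl
  a[rest] <- stats::runif(sum(rest), spec$area_core[2], spec$area_tail[2])
  round(a)
}

# rank-based digital ellipse: the `area` pixels closest to the center in the
# ellipse metric, so the rasterized pixel area equals the target exactly
ellipse_pixels <- function(cx, cy, a_semi, b_semi, area, width, height) {
  rx <- ceiling(a_semi) + 1L
  ry <- ceiling(b_semi) + 1L
  cols <- max(0L, floor(cx - rx)):min(width - 1L, ceiling(cx + rx))
  rows <- max(0L, floor(cy - ry)):min(height - 1L, ceiling(cy + ry))
  px <- expand.grid(x = cols, y = rows)
  m <- ((px$x + 0.5 - cx) / a_semi)^2 + ((px$y + 0.5 - cy) / b_semi)^2
  px[order(m)[seq_len(min(area, nrow(px)))], , drop = FALSE]
}

#' Generate a synthetic scene with ground truth
#'
#' Renders `n_flowers` non-overlapping reddish elliptical blobs over a
#' branch-textured background, together with the exact binary annotation
#' mask and the ground-truth pixel bounding boxes. Placement is by
#' rejection sampling: centroids are drawn uniformly over the allowed
#' region, and a candidate is retried when it would overlap an existing
#' flower (2 px clearance), cross the image border, or (when
#' `avoid_tile_borders`) cross a tile boundary.
#'
#' @param spec a [scene_spec()].
#' @param max_tries placement attempts per flower before giving up.
#' @return list with `image` (H x W x 3 array in `[0, 1]`, or `NULL` when
#'   `spec$render` is `FALSE`), `mask` (H x W 0/1 integer matrix), and
#'   `boxes` (ground-truth [pixel_box()] rows, one per flower).
#' @export
generate_scene <- function(spec, max_tries = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  W <- spec$width; H <- spec$height; ts <- spec$tile_size
  mask <- matrix(0L, nrow = H, ncol = W)
  img <- if (spec$render) render_background(W, H) else NULL
  areas <- sample_flower_areas(spec$n_flowers, spec)
  bx <- vector("list", spec$n_flowers)
  for (k in seq_len(spec$n_flowers)) {
    aspect <- stats::runif(1, spec$aspect_range[1], spec$aspect_range[2])
    b_semi <- sqrt(areas[k] / (pi * aspect))
    a_semi <- aspect * b_semi
    ex <- ceiling(a_semi) + 1L; ey <- ceiling(b_semi) + 1L
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, spec$margin + ex, W - spec$margin - ex)
      cy <- stats::runif(1, spec$margin + ey, H - spec$margin - ey)
      if (spec$avoid_tile_borders &&
          (floor((cx - ex) / ts) != floor((cx + ex) / ts) ||
           floor((cy - ey) / ts) != floor((cy + ey) / ts))) next
      # 2 px clearance so neighboring flowers never 8-connect
      rows <- max(1L, floor(cy - ey) - 1L):min(H, ceiling(cy + ey) + 2L)
      cols <- max(1L, floor(cx - ex) - 1L):min(W, ceiling(cx + ex) + 2L)
      if (any(mask[rows, cols] > 0)) next
      px <- ellipse_pixels(cx, cy, a_semi, b_semi, areas[k], W, H)
      mask[cbind(px$y + 1L, px$x + 1L)] <- 1L
      if (!is.null(img)) {
        col_f <- c(stats::runif(1, 0.50, 0.80), stats::runif(1, 0.10, 0.25),
                   stats::runif(1, 0.10, 0.25))
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[cbind(px$y + 1L, px$x + 1L)] <-
            clamp01(col_f[ch] + stats::rnorm(nrow(px), 0, 0.03))
          img[, , ch] <- plane
        }
      }
      bx[[k]] <- data.frame(x_min = min(px$x), y_min = min(px$y),
                            x_max = max(px$x) + 1L, y_max = max(px$y) + 1L)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place flower %d of %d after %d attempts; scene too crowded",
                   k, spec$n_flowers, max_tries), call. = FALSE)
  }
  boxes <- if (spec$n_flowers == 0) pixel_box() else
    as_pixel_box(do.call(rbind, bx))
  list(image = img, mask = mask, boxes = boxes)
}

# brown/gray background with branch-like dark strokes and pixel noise
render_background <- function(W, H) {
  base <- c(0.38, 0.33, 0.28)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    img[, , ch] <- clamp01(base[ch] + stats::rnorm(H * W, 0, 0.04))
  n_branches <- max(1L, round(W * H / 8e4))
  for (b in seq_len(n_branches)) {
    x0 <- stats::runif(1, 0, W); y0 <- stats::runif(1, 0, H)
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 0.2, 0.6) * min(W, H)
    wd <- sample(2:5, 1)
    t <- seq(0, 1, length.out = ceiling(len))
    xs <- pmin(pmax(round(x0 + t * len * cos(ang)), 1), W)
    ys <- pmin(pmax(round(y0 + t * len * sin(ang)), 1), H)
    shade <- stats::runif(1, -0.18, -0.08)
    for (dx in seq_len(wd) - 1L) {
      xi <- pmin(xs + dx, W)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[cbind(ys, xi)] <- clamp01(plane[cbind(ys, xi)] + shade)
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Oracle-detector noise specification
#'
#' Controls how far the synthetic oracle departs from perfection, emulating
#' the failure modes of a real detector: missed flowers (occlusion, low
#' contrast), spurious boxes (buds or branches mistaken for flowers), and
#' localization jitter. All zero by default: the zero-noise oracle returns
#' the ground truth exactly, with confidence 1.
#'
#' @param miss_rate probability of dropping each true flower.
#' @param fp_rate expected number of false boxes per tile (Poisson).
#' @param jitter_sd Gaussian sigma, px, added to each kept box's position.
#' @param conf_true `NULL` for constant confidence 1, or `c(shape1, shape2)`
#'   of a Beta distribution for true-detection confidences.
#' @param conf_false Beta parameters for false-detection confidences
#'   (default `c(2, 5)`: mostly below the 0.5 cutoff, as misdetections
#'   typically score low).
#' @param seed integer seed driving all detector randomness.
#' @return list with class `oracle_noise`.
#' @export
oracle_noise <- function(miss_rate = 0, fp_rate = 0, jitter_sd = 0,
                         conf_true = NULL, conf_false = c(2, 5), seed = 1L) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, jitter_sd >= 0)
  structure(list(miss_rate = miss_rate, fp_rate = fp_rate,
                 jitter_sd = jitter_sd, conf_true = conf_true,
                 conf_false = conf_false, seed = as.integer(seed)),
            class = "oracle_noise")
}

#' Build an oracle detector from ground truth
#'
#' Returns a detector satisfying the [detect_tiles()] contract that "sees"
#' the supplied ground-truth boxes instead of running a neural network: per
#' tile, each true box (clipped to the tile) is kept with probability
#' `1 - miss_rate`, jittered, and scored from the true-confidence model;
#' Poisson-distributed false boxes are added with low confidences. Each
#' tile's randomness is seeded from `(noise$seed, row, col)`, so results are
#' independent of tile processing order and reproducible call after call.
#'
#' @param gt_boxes global-frame ground-truth [pixel_box()] rows (e.g. from
#'   [generate_scene()]).
#' @param image_width,image_height scene dimensions in pixels.
#' @param noise an [oracle_noise()] specification.
#' @param tile_size tile side the detector will be run at (default 400).
#' @return a function `(tile_image, row, col) -> detections data frame`.
#' @export
make_oracle_detector <- function(gt_boxes, image_width, image_height,
                                 noise = oracle_noise(), tile_size = 400L) {
  stopifnot(inherits(noise, "oracle_noise"))
  gt_boxes <- as_pixel_box(gt_boxes)
  grid <- plan_tile_grid(image_width, image_height, tile_size)
  local_gt <- vector("list", grid$n_tiles)
  for (row in seq_len(grid$n_rows) - 1L)
    for (col in seq_len(grid$n_cols) - 1L)
      local_gt[[row * grid$n_cols + col + 1L]] <-
        clip_box_to_tile(gt_boxes, row, col, grid)
  ts <- grid$tile_size

  function(tile_image, row, col) {
    check_tile_index(row, col, grid)
    gl <- local_gt[[row * grid$n_cols + col + 1L]]
    tile_seed <- (abs(noise$seed) * 48271 + row * 10007 + col * 101 + 1) %%
      2147483647
    with_seed(tile_seed, {
      keep <- if (nrow(gl) == 0) logical(0) else
        stats::runif(nrow(gl)) >= noise$miss_rate
      out <- gl[keep, , drop = FALSE]
      n <- nrow(out)
      if (n > 0 && noise$jitter_sd > 0) {
        dx <- stats::rnorm(n, 0, noise$jitter_sd)
        dy <- stats::rnorm(n, 0, noise$jitter_sd)
        # translate, then clamp the shift so boxes stay inside the tile
        dx <- pmin(pmax(dx, -out$x_min), ts - out$x_max)
        dy <- pmin(pmax(dy, -out$y_min), ts - out$y_max)
        out$x_min <- out$x_min + dx; out$x_max <- out$x_max + dx
        out$y_min <- out$y_min + dy; out$y_max <- out$y_max + dy
      }
      conf <- if (is.null(noise$conf_true)) rep(1.0, n) else
        stats::rbeta(n, noise$conf_true[1], noise$conf_true[2])
      det <- as.data.frame(out)
      det$confidence <- conf
      n_fp <- if (noise$fp_rate > 0) stats::rpois(1, noise$fp_rate) else 0L
      if (n_fp > 0) {
        side_w <- sqrt(stats::runif(n_fp, 150, 500))
        side_h <- sqrt(stats::runif(n_fp, 150, 500))
        x0 <- stats::runif(n_fp, 0, ts - side_w)
        y0 <- stats::runif(n_fp, 0, ts - side_h)
        fp <- data.frame(x_min = x0, y_min = y0,
                         x_max = x0 + side_w, y_max = y0 + side_h,
                         confidence = stats::rbeta(n_fp, noise$conf_false[1],
                                                   noise$conf_false[2]))
        det <- rbind(det, fp)
      }
      rownames(det) <- NULL
      det
    })
  }
}

#' Specify a per-plant counting scenario
#'
#' Describes how raw two-side pipeline totals relate to the true per-plant
#' flower count, in the style of the seven-plant field validation: each
#' flower faces one side of the plant, is visible on its facing side with
#' probability `visible_fraction`, may additionally be seen from the
#' opposite side (`double_count_fraction`), and each visible flower is
#' detected with probability `1 - miss_rate`; spurious detections arrive at
#' `fp_per_side` per side. The defaults imply an expected raw total of
#' about half the true count — the systematic undercount (slope ~2 after
#' correction) observed in the field.
#'
#' Alternatively, supply `bias = list(slope, intercept, sigma)` to generate
#' reference counts directly from raw totals through a known linear map
#' plus Gaussian noise (reference values are rounded to quarters, as
#' averages of four integer operator counts are): the regression-recovery
#' path used to validate [fit_ols()].
#'
#' @param count_range true per-plant flower count range (uniform; default
#'   150-650, the span of the field reference counts).
#' @param visible_fraction probability a flower is visible on its facing
#'   side.
#' @param double_count_fraction probability it is also visible from the
#'   opposite side (counted twice).
#' @param miss_rate detector miss probability for a visible flower.
#' @param fp_per_side expected false detections per side (Poisson).
#' @param bias `NULL` (mechanistic model above) or
#'   `list(slope =, intercept =, sigma =)` for the direct linear model.
#' @param raw_range raw-total range used in `bias` mode (default 60-330).
#' @param seed integer seed.
#' @return list with class `plant_scenario`.
#' @export
plant_scenario <- function(count_range = c(150, 650), visible_fraction = 0.48,
                           double_count_fraction = 0.04, miss_rate = 0.05,
                           fp_per_side = 1, bias = NULL,
                           raw_range = c(60, 330), seed = 1L) {
  stopifnot(visible_fraction >= 0, visible_fraction <= 1,
            double_count_fraction >= 0, double_count_fraction <= 1,
            miss_rate >= 0, miss_rate <= 1, fp_per_side >= 0)
  structure(list(count_range = count_range,
                 visible_fraction = visible_fraction,
                 double_count_fraction = double_count_fraction,
                 miss_rate = miss_rate, fp_per_side = fp_per_side,
                 bias = bias, raw_range = raw_range, seed = as.integer(seed)),
            class = "plant_scenario")
}

#' Expected linear bias implied by a mechanistic scenario
#'
#' Under the mechanistic visibility model,
#' `E[raw] = T (v + d)(1 - m) + 2 f`, so the correcting line
#' `truth = slope * raw + intercept` has
#' `slope = 1 / ((v + d)(1 - m))` and `intercept = -2 f * slope`.
#'
#' @param scenario a [plant_scenario()] with `bias = NULL`.
#' @return list with `slope` and `intercept`.
#' @export
scenario_implied_bias <- function(scenario) {
  stopifnot(inherits(scenario, "plant_scenario"))
  if (!is.null(scenario$bias)) return(scenario$bias[c("slope", "intercept")])
  s <- 1 / ((scenario$visible_fraction + scenario$double_count_fraction) *
              (1 - scenario$miss_rate))
  list(slope = s, intercept = -2 * scenario$fp_per_side * s)
}

#' Simulate per-plant two-side counts
#'
#' Draws `n_plants` plants from a [plant_scenario()] and returns the table
#' the calibration module consumes: per-side raw counts, raw totals and
#' reference counts. Deterministic for a fixed scenario seed.
#'
#' @param scenario a [plant_scenario()].
#' @param n_plants number of plants to simulate.
#' @return data frame with columns `plant_id`, `side_a`, `side_b`,
#'   `raw_total`, `reference`.
#' @export
simulate_plant_counts <- function(scenario, n_plants = 7L) {
  stopifnot(inherits(scenario, "plant_scenario"), n_plants >= 1)
  old <- local_seed(scenario$seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- as.integer(n_plants)
  if (!is.null(scenario$bias)) {
    b <- scenario$bias
    raw <- round(stats::runif(n, scenario$raw_range[1], scenario$raw_range[2]))
    reference <- b$slope * raw + b$intercept + stats::rnorm(n, 0, b$sigma)
    reference <- round(reference * 4) / 4   # average of 4 integer counts
    f <- stats::runif(n, 0.3, 0.7)
    side_a <- stats::rbinom(n, raw, f)
    side_b <- raw - side_a
  } else {
    truth <- round(stats::runif(n, scenario$count_range[1],
                                scenario$count_range[2]))
    v <- scenario$visible_fraction
    d <- scenario$double_count_fraction
    p_det <- 1 - scenario$miss_rate
    side_a <- integer(n); side_b <- integer(n)
    for (i in seq_len(n)) {
      facing_a <- stats::runif(truth[i]) < 0.5
      seen_facing <- stats::runif(truth[i]) < v & stats::runif(truth[i]) < p_det
      seen_opp <- stats::runif(truth[i]) < d & stats::runif(truth[i]) < p_det
      side_a[i] <- sum(seen_facing & facing_a) + sum(seen_opp & !facing_a) +
        stats::rpois(1, scenario$fp_per_side)
      side_b[i] <- sum(seen_facing & !facing_a) + sum(seen_opp & facing_a) +
        stats::rpois(1, scenario$fp_per_side)
    }
    raw <- side_a + side_b
    reference <- truth
  }
  data.frame(plant_id = seq_len(n), side_a = as.integer(side_a),
             side_b = as.integer(side_b), raw_total = as.integer(raw),
             reference = as.numeric(reference))
}
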