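test_that("scenes are deterministic, mask-consistent and border-safe", {
  spec <- scene_spec(n_flowers = 12, seed = 42)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$image, s2$image)
  expect_equal(s1$boxes, s2$boxes)

  expect_equal(nrow(s1$boxes), 12)
  expect_equal(nrow(mask_to_boxes(s1$mask)), 12)
  expect_true(all(s1$mask %in% c(0L, 1L)))
  expect_equal(dim(s1$image), c(1200, 1600, 3))

  # ground-truth boxes equal the mask's component rectangles
  expect_equal(canon_boxes(mask_to_boxes(s1$mask, normalized = FALSE)),
               canon_boxes(s1$boxes))

  # no flower straddles a tile border when avoidance is on
  for (i in seq_len(nrow(s1$boxes)))
    expect_identical(c(s1$boxes$x_min[i] %/% 400, s1$boxes$y_min[i] %/% 400),
                     c((s1$boxes$x_max[i] - 1) %/% 400,
                       (s1$boxes$y_max[i] - 1) %/% 400))

  empty <- generate_scene(scene_spec(n_flowers = 0, seed = 1, render = FALSE))
  expect_equal(sum(empty$mask), 0)
  expect_equal(nrow(empty$boxes), 0)
})

test_that("flower areas put ~83% of mass in 280-320 px^2", {
  sc <- generate_scene(scene_spec(width = 3200, height = 2000, n_flowers = 500,
                                  render = FALSE, seed = 77))
  lab <- hazelcount:::cc_label_8(sc$mask)
  areas <- tabulate(lab[lab > 0])
  expect_length(areas, 500)
  frac <- mean(areas >= 280 & areas <= 320)
  expect_gte(frac, 0.78)
  expect_lte(frac, 0.88)
  # typical diameter ~17-20 px: box sides confined to a plausible range
  sides <- c(sc$boxes$x_max - sc$boxes$x_min, sc$boxes$y_max - sc$boxes$y_min)
  expect_true(all(sides >= 10 & sides <= 32))
})

test_that("scene centroids spread uniformly across tiles", {
  sc <- generate_scene(scene_spec(width = 3200, height = 2000, n_flowers = 500,
                                  render = FALSE, seed = 5))
  cx <- (sc$boxes$x_min + sc$boxes$x_max) / 2
  cy <- (sc$boxes$y_min + sc$boxes$y_max) / 2
  tile <- floor(cx / 400) + 8 * floor(cy / 400)
  counts <- tabulate(tile + 1, nbins = 40)
  # chi-square uniformity check, generous alpha for a fixed seed
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.999, df = 39))
})

test_that("placement failure is reported when the scene cannot fit", {
  expect_error(generate_scene(scene_spec(width = 420, height = 420,
                                         n_flowers = 400, render = FALSE,
                                         seed = 1)),
               "could not place")
})

test_that("oracle detector obeys its noise specification", {
  sc <- generate_scene(scene_spec(n_flowers = 25, seed = 10, render = FALSE))

  # zero noise: ground truth, confidence 1
  det0 <- make_oracle_detector(sc$boxes, 1600, 1200)
  d0 <- detect_tiles(det0, sc$mask)
  expect_equal(canon_boxes(d0), canon_boxes(sc$boxes))
  expect_true(all(d0$confidence == 1))

  # certain miss: silence
  det_miss <- make_oracle_detector(sc$boxes, 1600, 1200,
                                   oracle_noise(miss_rate = 1, seed = 2))
  expect_equal(nrow(detect_tiles(det_miss, sc$mask)), 0)

  # determinism and tile-order independence: repeated calls agree
  noisy <- make_oracle_detector(sc$boxes, 1600, 1200,
                                oracle_noise(miss_rate = 0.3, fp_rate = 0.7,
                                             jitter_sd = 1, conf_true = c(9, 2),
                                             seed = 11))
  expect_identical(detect_tiles(noisy, sc$mask), detect_tiles(noisy, sc$mask))

  # jittered boxes stay inside their tiles (contract not violated)
  expect_silent(detect_tiles(noisy, sc$mask, counting_config(confidence_threshold = 0)))
})

test_that("miss rate 0.2 detects a 0.80 +/- 0.02 fraction of 2000 flowers", {
  sc <- generate_scene(scene_spec(width = 6400, height = 4000, n_flowers = 2000,
                                  render = FALSE, seed = 19))
  det <- make_oracle_detector(sc$boxes, 6400, 4000,
                              oracle_noise(miss_rate = 0.2, seed = 23))
  found <- nrow(detect_tiles(det, sc$mask))
  expect_gte(found / 2000, 0.78)
  expect_lte(found / 2000, 0.82)
})

test_that("simulated plant counts honor their scenario", {
  # perfect visibility, no noise: raw totals equal the reference
  perfect <- plant_scenario(visible_fraction = 1, double_count_fraction = 0,
                            miss_rate = 0, fp_per_side = 0, seed = 31)
  tab <- simulate_plant_counts(perfect, 10)
  expect_equal(tab$raw_total, tab$reference)
  expect_equal(tab$side_a + tab$side_b, tab$raw_total)

  # byte-identical across runs
  sc7 <- plant_scenario(seed = 4)
  expect_identical(simulate_plant_counts(sc7, 7), simulate_plant_counts(sc7, 7))

  # low visibility: systematic undercount recovered with slope > 1
  occluded <- plant_scenario(visible_fraction = 0.3,
                             double_count_fraction = 0, miss_rate = 0,
                             fp_per_side = 0, seed = 8)
  tab2 <- simulate_plant_counts(occluded, 200)
  expect_true(all(tab2$raw_total < tab2$reference))
  m <- fit_ols(tab2$raw_total, tab2$reference)
  implied <- scenario_implied_bias(occluded)
  expect_gt(m$slope, 1)
  expect_equal(m$slope, implied$slope, tolerance = 0.12)
})

test_that("the default scenario undercounts like the field data (slope ~2)", {
  tab <- simulate_plant_counts(plant_scenario(seed = 12), 200)
  m <- fit_ols(tab$raw_total, tab$reference)
  implied <- scenario_implied_bias(plant_scenario())
  expect_equal(implied$slope, 2.0242915, tolerance = 1e-6)
  expect_equal(m$slope, implied$slope, tolerance = 0.15)
})

test_that("end-to-end: scene -> oracle -> metrics are perfect at zero noise", {
  sc <- generate_scene(scene_spec(n_flowers = 40, seed = 50, render = FALSE))
  det <- make_oracle_detector(sc$boxes, 1600, 1200)
  d <- detect_tiles(det, sc$mask)
  preds <- detections(d[c("x_min", "y_min", "x_max", "y_max")], d$confidence)
  m <- match_detections(preds, sc$boxes, 0.5)
  expect_equal(precision(m), 1.0)
  expect_equal(recall(m), 1.0)
  expect_equal(map_50_95(preds, sc$boxes), 1.0)
})
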