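test_that("iou matches hand arithmetic and is symmetric", {
  a <- pixel_box(0, 0, 2, 2)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, pixel_box(10, 10, 12, 12)), 0.0)
  b <- pixel_box(1, 0, 3, 2)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(iou(b, a), 1 / 3)
  # touching boxes share zero area
  expect_equal(iou(a, pixel_box(2, 0, 4, 2)), 0.0)
})

test_that("greedy matching handles the forced cases", {
  gts <- pixel_box(x_min = c(0, 100), y_min = 0, x_max = c(10, 110), y_max = 10)
  perfect <- detections(gts, confidence = c(0.9, 0.8))
  m <- match_detections(perfect, gts, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(2, 0, 0))
  expect_equal(precision(m), 1.0)
  expect_equal(recall(m), 1.0)

  # two predictions on one ground truth: the second is an FP
  gt1 <- pixel_box(0, 0, 10, 10)
  two <- detections(pixel_box(x_min = c(0, 1), y_min = c(0, 0),
                              x_max = c(10, 11), y_max = c(10, 10)),
                    confidence = c(0.9, 0.8))
  m2 <- match_detections(two, gt1, 0.5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1, 1, 0))

  # degenerate conventions
  m0 <- match_detections(detections(pixel_box(), numeric()), pixel_box(), 0.5)
  expect_equal(precision(m0), 1.0)
  expect_equal(recall(m0), 1.0)

  expect_error(match_detections(two, gt1, 0), "0, 1")
  expect_error(match_detections(two, gt1, 1.5), "0, 1")
})

test_that("greedy matching equals brute-force assignment on random instances", {
  for (seed in 1:400) {
    inst <- random_match_instance(seed)
    M <- hazelcount:::iou_matrix(inst$preds[1:4], inst$gts)
    for (thr in c(0.3, 0.5, 0.75)) {
      m <- match_detections(inst$preds, inst$gts, thr)
      expect_identical(m$TP, bf_max_matches(M, thr),
                       info = sprintf("seed %d thr %.2f", seed, thr))
      expect_identical(m$TP + m$FP, nrow(inst$preds))
      expect_identical(m$TP + m$FN, nrow(inst$gts))
      if (nrow(m$pairs)) expect_true(all(m$pairs$iou >= thr))
    }
  }
})

test_that("average precision reproduces the hand-computed sweeps", {
  gt1 <- pixel_box(0, 0, 10, 10)
  # 1 gt, one correct prediction below a higher-confidence false positive:
  # recall levels {1.0} with interpolated precision 0.5 -> AP = 0.5
  preds <- detections(pixel_box(x_min = c(500, 0), y_min = c(500, 0),
                                x_max = c(510, 10), y_max = c(510, 10)),
                      confidence = c(0.95, 0.60))
  expect_equal(average_precision(preds, gt1, 0.5), 0.5)

  # perfect detector -> AP 1 regardless of confidences
  gts <- pixel_box(x_min = c(0, 100, 200), y_min = 0,
                   x_max = c(10, 110, 210), y_max = 10)
  perfect <- detections(gts, confidence = c(0.51, 0.99, 0.7))
  expect_equal(average_precision(perfect, gts, 0.5), 1.0)
  expect_equal(map_50_95(perfect, gts), 1.0)

  # zero true positives -> AP 0
  off <- detections(pixel_box(900, 900, 910, 910), 0.9)
  expect_equal(average_precision(off, gts, 0.5), 0.0)
  # no predictions -> 0; no ground truth -> explicit error
  expect_equal(map_50_95(detections(pixel_box(), numeric()), gts), 0.0)
  expect_error(average_precision(perfect, pixel_box(), 0.5), "undefined")
})

test_that("IoU-0.70 staircase gives mAP@50-95 = 0.5", {
  # prediction contained in its gt with 70% of its area: IoU exactly 0.70
  n <- 4
  gts <- pixel_box(x_min = 100 * seq_len(n), y_min = 0,
                   x_max = 100 * seq_len(n) + 10, y_max = 10)
  preds <- detections(pixel_box(x_min = 100 * seq_len(n), y_min = 0,
                                x_max = 100 * seq_len(n) + 7, y_max = 10),
                      confidence = seq(0.9, 0.6, length.out = n))
  expect_equal(iou(preds[1, 1:4], gts[1, ]), 0.7)
  for (thr in seq(50L, 70L, 5L) / 100)
    expect_equal(average_precision(preds, gts, thr), 1.0)
  for (thr in seq(75L, 95L, 5L) / 100)
    expect_equal(average_precision(preds, gts, thr), 0.0)
  expect_equal(map_50_95(preds, gts), 0.5)
})

test_that("AP is monotone in threshold and bounded by AP@50", {
  set.seed(21)
  for (rep in 1:10) {
    ng <- sample(3:6, 1)
    gts <- pixel_box(x_min = 100 * seq_len(ng), y_min = 0,
                     x_max = 100 * seq_len(ng) + 20, y_max = 20)
    np <- sample(2:8, 1)
    target <- sample(seq_len(ng), np, replace = TRUE)
    dx <- runif(np, 0, 15)
    preds <- detections(pixel_box(x_min = 100 * target + dx, y_min = dx,
                                  x_max = 100 * target + 20 + dx,
                                  y_max = 20 + dx),
                        confidence = runif(np))
    aps <- vapply(seq(50L, 95L, 5L) / 100,
                  function(t) average_precision(preds, gts, t), numeric(1))
    expect_true(all(diff(aps) <= 1e-12))
    expect_true(all(aps >= 0 & aps <= 1))
    expect_lte(map_50_95(preds, gts), aps[1] + 1e-12)
  }
})

test_that("metrics are invariant to prediction input order", {
  set.seed(33)
  ng <- 5
  gts <- pixel_box(x_min = 100 * seq_len(ng), y_min = 0,
                   x_max = 100 * seq_len(ng) + 20, y_max = 20)
  target <- sample(seq_len(ng), 9, replace = TRUE)
  dx <- runif(9, 0, 12)
  preds <- detections(pixel_box(x_min = 100 * target + dx, y_min = dx,
                                x_max = 100 * target + 20 + dx, y_max = 20 + dx),
                      confidence = round(runif(9), 2))  # rounded: forces ties
  base_ap <- vapply(seq(50L, 95L, 5L) / 100,
                    function(t) average_precision(preds, gts, t), numeric(1))
  base_m <- match_detections(preds, gts, 0.5)
  for (rep in 1:5) {
    sh <- preds[sample(nrow(preds)), ]
    class(sh) <- class(preds)
    m <- match_detections(sh, gts, 0.5)
    expect_identical(c(m$TP, m$FP, m$FN), c(base_m$TP, base_m$FP, base_m$FN))
    expect_equal(vapply(seq(50L, 95L, 5L) / 100,
                        function(t) average_precision(sh, gts, t), numeric(1)),
                 base_ap)
  }
})

test_that("average precision pools detections across images correctly", {
  gts <- rbind(data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                          image_id = "a"),
               data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                          image_id = "b"))
  # image a: hit; image b: the same box is a hit there, plus an FP in a
  preds <- detections(pixel_box(x_min = c(0, 0, 500), y_min = c(0, 0, 500),
                                x_max = c(10, 10, 510), y_max = c(10, 10, 510)),
                      confidence = c(0.9, 0.8, 0.7),
                      image_id = c("a", "b", "a"))
  expect_equal(average_precision(preds, gts, 0.5), 1.0)  # FP after full recall
})
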