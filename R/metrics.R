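#' Intersection over Union of two boxes
#'
#' IoU = |A intersect B| / |A union B|, the standard overlap score between a
#' predicted and a ground-truth box: 0 for disjoint boxes, 1 for identical
#' boxes. Vectorized over rows when `a` and `b` have the same number of rows.
#'
#' @param a,b [pixel_box()] data frames in the same coordinate frame.
#' @return numeric vector of IoU values in `[0, 1]`.
#' @examples
#' iou(pixel_box(0, 0, 2, 2), pixel_box(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as_pixel_box(a); b <- as_pixel_box(b)
  iw <- pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min)
  ih <- pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  inter / (box_area(a) + box_area(b) - inter)
}

# all-pairs IoU matrix: rows = preds, cols = gts
iou_matrix <- function(pred, gt) {
  pred <- as_pixel_box(pred); gt <- as_pixel_box(gt)
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) return(matrix(0, np, ng))
  iw <- pmax(outer(pred$x_max, gt$x_max, pmin) - outer(pred$x_min, gt$x_min, pmax), 0)
  ih <- pmax(outer(pred$y_max, gt$y_max, pmin) - outer(pred$y_min, gt$y_min, pmax), 0)
  inter <- iw * ih
  inter / (outer(box_area(pred), box_area(gt), "+") - inter)
}

#' Build a detection table
#'
#' A detection is a scored predicted box. Detections are plain data frames
#' with the [pixel_box()] columns plus `confidence` (and optionally
#' `image_id` when evaluating over an image set).
#'
#' @param box a [pixel_box()] data frame.
#' @param confidence numeric vector in `[0, 1]`, one per box: the detector's
#'   estimated probability that the box is a real object.
#' @param image_id optional identifier vector (recycled).
#' @return data frame with class `detections`.
#' @export
detections <- function(box, confidence, image_id = NULL) {
  box <- as_pixel_box(box)
  stopifnot(length(confidence) == nrow(box))
  if (nrow(box) > 0 && (any(confidence < 0) || any(confidence > 1)))
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  d <- as.data.frame(box)
  d$confidence <- as.numeric(confidence)
  if (!is.null(image_id)) d$image_id <- rep(image_id, length.out = nrow(d))
  class(d) <- c("detections", "data.frame")
  d
}

as_detections <- function(d) {
  if (!all(c("x_min", "y_min", "x_max", "y_max", "confidence") %in% names(d)))
    stop("detections need box columns plus confidence", call. = FALSE)
  detections(d[c("x_min", "y_min", "x_max", "y_max")], d$confidence,
             image_id = if ("image_id" %in% names(d)) d$image_id else NULL)
}

# deterministic processing order: descending confidence, ties by input index
confidence_order <- function(conf) order(-conf, seq_along(conf))

#' Match predictions to ground truth at an IoU threshold
#'
#' Implements the de-facto benchmark protocol (the greedy variant used by
#' standard detection evaluations): predictions are processed in descending
#' confidence (ties broken by input order); each is matched to the
#' still-unmatched ground-truth box of highest IoU, provided that IoU meets
#' the threshold. A matched prediction is a true positive (TP); an unmatched
#' prediction is a false positive (FP); an unmatched ground truth is a false
#' negative (FN). IoU ties between candidate ground truths are broken by
#' lower ground-truth index.
#'
#' @param preds a [detections()] data frame for one image.
#' @param gts a [pixel_box()] data frame of ground-truth boxes.
#' @param iou_threshold scalar in `(0, 1]`.
#' @return A `match_result`: list with counts `TP`, `FP`, `FN` and `pairs`,
#'   a data frame of matched `(pred, gt, iou)` index pairs.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  if (length(iou_threshold) != 1 || !is.finite(iou_threshold) ||
      iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  preds <- as_detections(preds)
  gts <- as_pixel_box(gts)
  np <- nrow(preds); ng <- nrow(gts)
  M <- iou_matrix(preds, gts)
  taken <- rep(FALSE, ng)
  pairs <- data.frame(pred = integer(), gt = integer(), iou = numeric())
  for (i in confidence_order(preds$confidence)) {
    if (ng == 0) break
    cand <- which(!taken & M[i, ] >= iou_threshold)
    if (length(cand) == 0) next
    best <- cand[order(-M[i, cand], cand)][1]
    taken[best] <- TRUE
    pairs <- rbind(pairs, data.frame(pred = i, gt = best, iou = M[i, best]))
  }
  res <- list(TP = nrow(pairs), FP = np - nrow(pairs), FN = ng - nrow(pairs),
              n_pred = np, n_gt = ng, pairs = pairs,
              iou_threshold = iou_threshold)
  class(res) <- "match_result"
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match @ IoU>=%.2f: TP=%d FP=%d FN=%d (precision %.3f, recall %.3f)\n",
              x$iou_threshold, x$TP, x$FP, x$FN, precision(x), recall(x)))
  invisible(x)
}

#' Precision and recall of a match result
#'
#' Precision = TP / (TP + FP); recall = TP / (TP + FN). Degenerate cases are
#' fixed by convention so downstream sweeps never divide by zero: with no
#' predictions precision is 1, and with no ground truths recall is 1.
#'
#' @param m a `match_result` from [match_detections()].
#' @return scalar in `[0, 1]`.
#' @export
precision <- function(m) {
  stopifnot(inherits(m, "match_result"))
  if (m$TP + m$FP == 0) return(1.0)
  m$TP / (m$TP + m$FP)
}

#' @rdname precision
#' @export
recall <- function(m) {
  stopifnot(inherits(m, "match_result"))
  if (m$TP + m$FN == 0) return(1.0)
  m$TP / (m$TP + m$FN)
}

# split detections / gts by image id (everything in one image when absent)
split_by_image <- function(preds, gts) {
  pid <- if ("image_id" %in% names(preds)) preds$image_id else rep(1L, nrow(preds))
  gid <- if ("image_id" %in% names(gts)) gts$image_id else rep(1L, nrow(gts))
  ids <- unique(c(pid, gid))
  lapply(ids, function(id) list(
    preds = preds[pid == id, , drop = FALSE],
    gts = as_pixel_box(gts[gid == id, c("x_min", "y_min", "x_max", "y_max"),
                           drop = FALSE])))
}

#' Average precision at one IoU threshold
#'
#' Sweeps a confidence cutoff over all distinct confidence values
#' (descending), accumulating TP/FP against the fixed set of ground truths;
#' at each observed recall level the interpolated precision is the envelope
#' `P(R) = max{ precision at recall >= R }`, and
#' `AP = sum_k P(R_k) * delta R_k` over the observed recall levels
#' (all-point interpolation). Matching within each image follows
#' [match_detections()]; because that protocol is greedy in confidence
#' order, the cumulative sweep equals re-matching from scratch at every
#' cutoff.
#'
#' @param preds a [detections()] data frame, optionally with `image_id`.
#' @param gts ground-truth [pixel_box()] rows, optionally with `image_id`.
#' @param iou_threshold scalar in `(0, 1]`.
#' @return scalar AP in `[0, 1]`.
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5) {
  preds <- as_detections(preds)
  n_gt <- nrow(gts)
  if (n_gt == 0)
    stop("average precision is undefined without ground-truth objects",
         call. = FALSE)
  if (nrow(preds) == 0) return(0.0)
  per_image <- split_by_image(preds, gts)
  conf <- numeric(); is_tp <- logical()
  for (im in per_image) {
    if (nrow(im$preds) == 0) next
    m <- match_detections(im$preds, im$gts, iou_threshold)
    tp <- rep(FALSE, nrow(im$preds))
    tp[m$pairs$pred] <- TRUE
    conf <- c(conf, im$preds$confidence)
    is_tp <- c(is_tp, tp)
  }
  o <- confidence_order(conf)
  conf <- conf[o]; is_tp <- is_tp[o]
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  # evaluate at the last detection of each distinct confidence value
  # (all detections with equal confidence enter the pool together)
  last <- which(conf != c(conf[-1], -1))
  rec <- cum_tp[last] / n_gt
  prec <- cum_tp[last] / (cum_tp[last] + cum_fp[last])
  # precision envelope: max precision at any recall >= R_k
  env <- rev(cummax(rev(prec)))
  sum(env * diff(c(0, rec)))
}

#' Mean average precision over IoU thresholds 0.50-0.95
#'
#' mAP@50-95: the mean of [average_precision()] over the ten IoU thresholds
#' 0.50, 0.55, ..., 0.95, averaged across classes (a single class here).
#' Stricter thresholds demand tighter localization, so this score summarizes
#' detection quality across degrees of strictness; it is never larger than
#' AP at threshold 0.50 alone.
#'
#' @inheritParams average_precision
#' @param thresholds IoU thresholds (default the ten-step 0.50-0.95 ladder).
#' @return scalar mAP in `[0, 1]`; 0 when there are no predictions.
#' @export
map_50_95 <- function(preds, gts, thresholds = seq(50L, 95L, 5L) / 100) {
  stopifnot(length(thresholds) >= 1)
  mean(vapply(thresholds, function(t) average_precision(preds, gts, t),
              numeric(1)))
}
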