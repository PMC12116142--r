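#' Counting configuration
#'
#' Bundles the two pipeline knobs: the tile size (400 px, chosen so a
#' 17-20 px flower occupies a usable fraction of each processed frame) and
#' the confidence cutoff (0.5; every prediction below it is discarded to
#' suppress false positives such as buds or branches).
#'
#' @param tile_size square tile side in pixels.
#' @param confidence_threshold detections below this confidence are dropped.
#' @return list with class `counting_config`.
#' @export
counting_config <- function(tile_size = 400L, confidence_threshold = 0.5) {
  if (confidence_threshold < 0 || confidence_threshold > 1)
    stop("confidence_threshold must lie in [0, 1]", call. = FALSE)
  structure(list(tile_size = as.integer(tile_size),
                 confidence_threshold = as.numeric(confidence_threshold)),
            class = "counting_config")
}

# Detector contract: a function(tile_image, row, col) returning a data frame
# with tile-local pixel-box columns plus confidence. Enforced per tile.
check_detector_output <- function(det, tile_size, row, col) {
  where <- sprintf("detector output for tile (row=%d, col=%d)", row, col)
  if (!is.data.frame(det) ||
      !all(c("x_min", "y_min", "x_max", "y_max", "confidence") %in% names(det)))
    stop(where, " must be a data frame with box columns and confidence",
         call. = FALSE)
  if (nrow(det) == 0) return(invisible(det))
  if (any(det$confidence < 0) || any(det$confidence > 1))
    stop(where, " has confidence outside [0, 1]", call. = FALSE)
  if (any(det$x_min < 0) || any(det$y_min < 0) ||
      any(det$x_max > tile_size) || any(det$y_max > tile_size) ||
      any(det$x_max <= det$x_min) || any(det$y_max <= det$y_min))
    stop(where, " has boxes outside the tile bounds", call. = FALSE)
  invisible(det)
}

#' Run a detector over every tile of an image
#'
#' Pads and tiles the image, applies the detector to each tile
#' independently, discards detections below the confidence threshold, and
#' maps the survivors back to global image coordinates. No cross-tile
#' merging or non-maximum suppression is performed: tiles are processed
#' independently, so an object straddling a tile border may be detected once
#' per tile (the downstream bias correction absorbs this).
#'
#' @param detector a function `(tile_image, row, col) -> data.frame` with
#'   tile-local box columns plus `confidence` (see [make_oracle_detector()]
#'   for the reference implementation of the contract).
#' @param image numeric matrix/array (H x W or H x W x C).
#' @param config a [counting_config()].
#' @return a [detections()] data frame in global coordinates with extra
#'   `row`/`col` columns recording the source tile.
#' @export
detect_tiles <- function(detector, image, config = counting_config()) {
  stopifnot(is.function(detector), inherits(config, "counting_config"))
  d <- image_dims(image)
  grid <- plan_tile_grid(d$width, d$height, config$tile_size)
  tiles <- split_into_tiles(pad_to_grid(image, grid), grid)
  out <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    det <- detector(t$image, t$row, t$col)
    check_detector_output(det, config$tile_size, t$row, t$col)
    det <- det[det$confidence >= config$confidence_threshold, , drop = FALSE]
    if (nrow(det) == 0) next
    gb <- tile_local_to_global(
      det[c("x_min", "y_min", "x_max", "y_max")], t$row, t$col, grid)
    res <- as.data.frame(gb)
    res$confidence <- det$confidence
    res$row <- t$row
    res$col <- t$col
    out[[i]] <- res
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    res <- as.data.frame(pixel_box())
    res$confidence <- numeric(); res$row <- integer(); res$col <- integer()
  } else {
    res <- do.call(rbind, out)
  }
  rownames(res) <- NULL
  class(res) <- c("detections", "data.frame")
  attr(res, "grid") <- grid
  res
}

#' Count flowers on one side of a plant
#'
#' The raw side count is simply the number of confidence-filtered detections
#' summed over all tiles of that side's image.
#'
#' @inheritParams detect_tiles
#' @param plant_id plant identifier.
#' @param side side label, `"a"` or `"b"` (the two opposite viewpoints).
#' @return a `side_count`: list with `plant_id`, `side`, `detections`
#'   (global-frame data frame), `raw_count`.
#' @export
count_side <- function(detector, image, config = counting_config(),
                       plant_id = 1L, side = "a") {
  side <- match.arg(side, c("a", "b"))
  det <- detect_tiles(detector, image, config)
  structure(list(plant_id = plant_id, side = side, detections = det,
                 raw_count = nrow(det)),
            class = "side_count")
}

#' @export
print.side_count <- function(x, ...) {
  cat(sprintf("plant %s side %s: %d flowers detected\n",
              format(x$plant_id), x$side, x$raw_count))
  invisible(x)
}

#' Combine the two side counts of a plant
#'
#' The plant's raw total is the plain sum of the two sides; no attempt is
#' made to deduplicate flowers visible from both sides (that systematic
#' bias, like occlusion losses, is corrected downstream by the regression
#' calibration).
#'
#' @param side_a,side_b `side_count` objects for the same plant.
#' @return a `plant_count`: list with `plant_id`, `side_a`, `side_b`,
#'   `raw_total` and (initially `NA`) `corrected_total`.
#' @export
count_plant <- function(side_a, side_b) {
  stopifnot(inherits(side_a, "side_count"), inherits(side_b, "side_count"))
  if (!identical(side_a$plant_id, side_b$plant_id))
    stop("side counts belong to different plants: ",
         format(side_a$plant_id), " vs ", format(side_b$plant_id),
         call. = FALSE)
  structure(list(plant_id = side_a$plant_id,
                 side_a = side_a$raw_count, side_b = side_b$raw_count,
                 raw_total = side_a$raw_count + side_b$raw_count,
                 corrected_total = NA_real_),
            class = "plant_count")
}

#' @export
print.plant_count <- function(x, ...) {
  cat(sprintf("plant %s: side a %d + side b %d = %d raw%s\n",
              format(x$plant_id), x$side_a, x$side_b, x$raw_total,
              if (is.na(x$corrected_total)) "" else
                sprintf(" (corrected %.2f)", x$corrected_total)))
  invisible(x)
}
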