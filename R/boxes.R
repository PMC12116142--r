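#' Axis-aligned pixel bounding boxes
#'
#' A `pixel_box` is a data frame of axis-aligned rectangles in 0-based,
#' half-open pixel coordinates: the pixel columns covered by a box are
#' `[x_min, x_max)` and the rows `[y_min, y_max)`. This convention makes
#' areas and intersections exact integer arithmetic and makes a tiling a
#' true partition of the image.
#'
#' @param x_min,y_min,x_max,y_max numeric vectors (recycled to a common
#'   length) with `x_min < x_max`, `y_min < y_max`, all values `>= 0`.
#' @return A data frame with class `pixel_box` and columns
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' b <- pixel_box(0, 0, 10, 20)
#' box_area(b)  # 200
#' @export
pixel_box <- function(x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric()) {
  b <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  class(b) <- c("pixel_box", "data.frame")
  validate_pixel_box(b)
  b
}

validate_pixel_box <- function(b) {
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(b)))
    stop("pixel box needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(b) == 0) return(invisible(b))
  if (any(!is.finite(as.matrix(b[need]))))
    stop("pixel box coordinates must be finite", call. = FALSE)
  if (any(b$x_min < 0) || any(b$y_min < 0))
    stop("pixel box coordinates must be >= 0", call. = FALSE)
  if (any(b$x_max <= b$x_min) || any(b$y_max <= b$y_min))
    stop("pixel box must have positive width and height (half-open [min, max))",
         call. = FALSE)
  invisible(b)
}

as_pixel_box <- function(b) {
  if (!inherits(b, "pixel_box")) {
    b <- as.data.frame(b)
    class(b) <- c("pixel_box", "data.frame")
  }
  validate_pixel_box(b)
  b
}

#' Box areas in pixels
#' @param b a [pixel_box()] data frame.
#' @return numeric vector of areas, one per row.
#' @export
box_area <- function(b) {
  b <- as_pixel_box(b)
  (b$x_max - b$x_min) * (b$y_max - b$y_min)
}

#' Normalized detection-label boxes
#'
#' The standard detection-label representation: class id plus box center and
#' size, each expressed as a fraction of the image (mask) width and height.
#' Coordinates lie in `[0, 1]` and every box must stay inside the unit
#' square (`x_c - w/2 >= 0`, `x_c + w/2 <= 1`, likewise for y).
#'
#' @param class_id integer vector (single-class pipelines use 0).
#' @param x_c,y_c box center as a fraction of image width / height.
#' @param w,h box width / height as fractions.
#' @return data frame with class `normalized_box`.
#' @export
normalized_box <- function(class_id = integer(), x_c = numeric(),
                           y_c = numeric(), w = numeric(), h = numeric()) {
  b <- data.frame(class_id = as.integer(class_id), x_c = as.numeric(x_c),
                  y_c = as.numeric(y_c), w = as.numeric(w), h = as.numeric(h))
  class(b) <- c("normalized_box", "data.frame")
  validate_normalized_box(b)
  b
}

# tol absorbs 6-decimal label rounding at the unit-square border
validate_normalized_box <- function(b, tol = 2e-6) {
  need <- c("class_id", "x_c", "y_c", "w", "h")
  if (!all(need %in% names(b)))
    stop("normalized box needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(b) == 0) return(invisible(b))
  bad <- b$w <= 0 | b$h <= 0 |
    b$x_c - b$w / 2 < -tol | b$x_c + b$w / 2 > 1 + tol |
    b$y_c - b$h / 2 < -tol | b$y_c + b$h / 2 > 1 + tol
  if (any(bad))
    stop("normalized box outside [0,1]^2 or with non-positive size (row ",
         which(bad)[1], ")", call. = FALSE)
  invisible(b)
}

#' Convert pixel boxes to normalized label coordinates
#'
#' @param b a [pixel_box()] data frame.
#' @param image_width,image_height image dimensions in pixels.
#' @param class_id class id to assign (default 0, the only class here).
#' @return a [normalized_box()] data frame.
#' @export
normalize_boxes <- function(b, image_width, image_height, class_id = 0L) {
  b <- as_pixel_box(b)
  normalized_box(class_id = rep(as.integer(class_id), nrow(b)),
                 x_c = (b$x_min + b$x_max) / 2 / image_width,
                 y_c = (b$y_min + b$y_max) / 2 / image_height,
                 w = (b$x_max - b$x_min) / image_width,
                 h = (b$y_max - b$y_min) / image_height)
}

#' Convert normalized label boxes back to pixel coordinates
#'
#' Inverse of [normalize_boxes()] (up to label-precision rounding).
#'
#' @param b a [normalized_box()] data frame.
#' @param image_width,image_height image dimensions in pixels.
#' @return a [pixel_box()] data frame.
#' @export
denormalize_boxes <- function(b, image_width, image_height) {
  validate_normalized_box(b)
  pixel_box(x_min = pmax(0, (b$x_c - b$w / 2) * image_width),
            y_min = pmax(0, (b$y_c - b$h / 2) * image_height),
            x_max = (b$x_c + b$w / 2) * image_width,
            y_max = (b$y_c + b$h / 2) * image_height)
}
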