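#' Plan the square tiling of a high-resolution image
#'
#' Whole-plant images are far too large for a detector that must resolve
#' flowers ~17-20 px across, so each image is partitioned into square tiles
#' (default 400 px), padding the right and bottom edges when the image
#' dimensions are not multiples of the tile size. The reference 8256 x 5504
#' px frame yields a 21 x 14 grid of 294 tiles.
#'
#' @param image_width,image_height image dimensions in pixels (positive
#'   integers).
#' @param tile_size square tile side in pixels (default 400).
#' @return A `tile_grid` object: list with `image_width`, `image_height`,
#'   `tile_size`, `n_cols`, `n_rows`, `pad_right`, `pad_bottom`, `n_tiles`.
#' @examples
#' g <- plan_tile_grid(8256, 5504, 400)
#' g$n_tiles  # 294
#' @export
plan_tile_grid <- function(image_width, image_height, tile_size = 400L) {
  for (v in list(image_width, image_height, tile_size)) {
    if (length(v) != 1 || !is.finite(v) || v <= 0 || v != as.integer(v))
      stop("image dimensions and tile size must be positive integers",
           call. = FALSE)
  }
  image_width <- as.integer(image_width)
  image_height <- as.integer(image_height)
  tile_size <- as.integer(tile_size)
  n_cols <- as.integer(ceiling(image_width / tile_size))
  n_rows <- as.integer(ceiling(image_height / tile_size))
  g <- list(image_width = image_width, image_height = image_height,
            tile_size = tile_size, n_cols = n_cols, n_rows = n_rows,
            pad_right = n_cols * tile_size - image_width,
            pad_bottom = n_rows * tile_size - image_height,
            n_tiles = n_cols * n_rows)
  class(g) <- "tile_grid"
  g
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile grid: %d x %d px, tile %d px -> %d cols x %d rows = %d tiles (pad right %d, bottom %d)\n",
              x$image_width, x$image_height, x$tile_size,
              x$n_cols, x$n_rows, x$n_tiles, x$pad_right, x$pad_bottom))
  invisible(x)
}

image_dims <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2 || length(d) > 3)
    stop("image must be a matrix (H x W) or array (H x W x C)", call. = FALSE)
  list(height = d[1], width = d[2], channels = if (length(d) == 3) d[3] else 1L)
}

#' Pad an image to a whole number of tiles
#'
#' Pads the right and bottom edges with zeros (black) so that the image
#' measures exactly `n_cols * tile_size` by `n_rows * tile_size`. The origin
#' is fixed: every original pixel keeps its coordinates.
#'
#' @param image numeric matrix (H x W) or array (H x W x C); rows are y,
#'   columns are x, as returned by [png::readPNG()].
#' @param grid a [plan_tile_grid()] result matching the image dimensions.
#' @param fill fill value for padded pixels (default 0, black).
#' @return padded matrix/array.
#' @export
pad_to_grid <- function(image, grid, fill = 0) {
  stopifnot(inherits(grid, "tile_grid"))
  d <- image_dims(image)
  if (d$width != grid$image_width || d$height != grid$image_height)
    stop(sprintf("image is %d x %d but grid expects %d x %d",
                 d$width, d$height, grid$image_width, grid$image_height),
         call. = FALSE)
  out_w <- grid$n_cols * grid$tile_size
  out_h <- grid$n_rows * grid$tile_size
  if (out_w == d$width && out_h == d$height) return(image)
  if (d$channels == 1L && length(dim(image)) == 2) {
    out <- matrix(fill, nrow = out_h, ncol = out_w)
    out[seq_len(d$height), seq_len(d$width)] <- image
  } else {
    out <- array(fill, dim = c(out_h, out_w, d$channels))
    out[seq_len(d$height), seq_len(d$width), ] <- image
  }
  out
}

#' Split a padded image into tiles
#'
#' Tiles are emitted in row-major order from the top-left; tile `(row, col)`
#' (0-based) covers global pixels
#' `[col * tile_size, (col+1) * tile_size) x [row * tile_size, (row+1) * tile_size)`.
#' The tiles partition the padded image exactly: [assemble_tiles()] restores
#' it bit for bit.
#'
#' @param image padded matrix/array (dimensions must be
#'   `n_rows * tile_size` x `n_cols * tile_size`); see [pad_to_grid()].
#' @param grid a [plan_tile_grid()] result.
#' @return list of length `n_tiles`; each element is
#'   `list(index, row, col, image)` with `row`/`col` 0-based.
#' @export
split_into_tiles <- function(image, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  d <- image_dims(image)
  ts <- grid$tile_size
  if (d$width != grid$n_cols * ts || d$height != grid$n_rows * ts)
    stop(sprintf("image is %d x %d; expected padded size %d x %d (use pad_to_grid first)",
                 d$width, d$height, grid$n_cols * ts, grid$n_rows * ts),
         call. = FALSE)
  tiles <- vector("list", grid$n_tiles)
  k <- 1L
  for (row in seq_len(grid$n_rows) - 1L) {
    rows <- row * ts + seq_len(ts)
    for (col in seq_len(grid$n_cols) - 1L) {
      cols <- col * ts + seq_len(ts)
      tile <- if (d$channels == 1L && length(dim(image)) == 2)
        image[rows, cols, drop = FALSE]
      else image[rows, cols, , drop = FALSE]
      tiles[[k]] <- list(index = k, row = row, col = col, image = tile)
      k <- k + 1L
    }
  }
  attr(tiles, "grid") <- grid
  tiles
}

#' Reassemble tiles into the padded image
#'
#' Inverse of [split_into_tiles()]; used to assert the partition property.
#'
#' @param tiles list produced by [split_into_tiles()].
#' @param grid a [plan_tile_grid()] result (defaults to the grid attached to
#'   `tiles`).
#' @return the padded matrix/array.
#' @export
assemble_tiles <- function(tiles, grid = attr(tiles, "grid")) {
  stopifnot(inherits(grid, "tile_grid"), length(tiles) == grid$n_tiles)
  ts <- grid$tile_size
  d <- image_dims(tiles[[1]]$image)
  out <- if (d$channels == 1L && length(dim(tiles[[1]]$image)) == 2)
    matrix(0, nrow = grid$n_rows * ts, ncol = grid$n_cols * ts)
  else array(0, dim = c(grid$n_rows * ts, grid$n_cols * ts, d$channels))
  for (t in tiles) {
    rows <- t$row * ts + seq_len(ts)
    cols <- t$col * ts + seq_len(ts)
    if (length(dim(out)) == 2) out[rows, cols] <- t$image
    else out[rows, cols, ] <- t$image
  }
  out
}

check_tile_index <- function(row, col, grid) {
  if (length(row) != 1 || length(col) != 1 ||
      row < 0 || row >= grid$n_rows || col < 0 || col >= grid$n_cols)
    stop(sprintf("tile (row=%s, col=%s) outside grid %d x %d",
                 row, col, grid$n_rows, grid$n_cols), call. = FALSE)
}

#' Translate tile-local boxes to global image coordinates
#'
#' @param box a [pixel_box()] in tile-local coordinates
#'   (within `[0, tile_size)^2`).
#' @param row,col 0-based tile indices.
#' @param grid a [plan_tile_grid()] result.
#' @return the boxes translated by `(col * tile_size, row * tile_size)`.
#' @export
tile_local_to_global <- function(box, row, col, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  check_tile_index(row, col, grid)
  box <- as_pixel_box(box)
  if (nrow(box) > 0 &&
      (any(box$x_max > grid$tile_size) || any(box$y_max > grid$tile_size)))
    stop("tile-local box exceeds the tile extent", call. = FALSE)
  pixel_box(box$x_min + col * grid$tile_size,
            box$y_min + row * grid$tile_size,
            box$x_max + col * grid$tile_size,
            box$y_max + row * grid$tile_size)
}

#' Clip global boxes to one tile
#'
#' Intersects global-frame boxes with the pixel extent of tile `(row, col)`
#' and expresses the surviving fragments in tile-local coordinates. Boxes
#' that merely touch the tile (zero-area intersection) are dropped, so an
#' object crossing a tile border contributes one fragment per tile it
#' overlaps, and the fragment areas sum to the original box area.
#'
#' @param box a global-frame [pixel_box()].
#' @param row,col 0-based tile indices.
#' @param grid a [plan_tile_grid()] result.
#' @return a tile-local [pixel_box()]; zero rows when nothing intersects.
#' @export
clip_box_to_tile <- function(box, row, col, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  check_tile_index(row, col, grid)
  box <- as_pixel_box(box)
  ts <- grid$tile_size
  x0 <- col * ts; y0 <- row * ts
  x_min <- pmax(box$x_min, x0); x_max <- pmin(box$x_max, x0 + ts)
  y_min <- pmax(box$y_min, y0); y_max <- pmin(box$y_max, y0 + ts)
  keep <- x_min < x_max & y_min < y_max
  pixel_box(x_min[keep] - x0, y_min[keep] - y0,
            x_max[keep] - x0, y_max[keep] - y0)
}
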