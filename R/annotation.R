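#' Convert a binary annotation mask into bounding boxes
#'
#' Field annotation produces binary masks in which foreground pixels mark
#' female-flower regions. Each 8-connected foreground component is enclosed
#' by its minimal axis-aligned rectangle; rectangles are reported either as
#' pixel boxes or as normalized label coordinates (class 0).
#' 8-connectivity is used so diagonal pixel chains of the tiny blobs are not
#' split into multiple objects.
#'
#' @param mask matrix of 0/1 (or logical); rows are y, columns are x.
#' @param normalized return [normalized_box()] coordinates (default) or raw
#'   [pixel_box()] extents.
#' @param min_area drop components smaller than this pixel area (default 0:
#'   keep everything, including single-pixel fragments created by tile
#'   clipping).
#' @return a [normalized_box()] or [pixel_box()] data frame, one row per
#'   connected component, ordered by first pixel in column-major scan order.
#' @examples
#' m <- matrix(0L, 20, 20); m[11:13, 11:13] <- 1L
#' mask_to_boxes(m, normalized = FALSE)  # pixel extent (10, 10, 13, 13)
#' @export
mask_to_boxes <- function(mask, normalized = TRUE, min_area = 0) {
  if (is.logical(mask)) mask <- mask + 0L
  if (!is.matrix(mask) && !(is.array(mask) && length(dim(mask)) == 2))
    stop("mask must be a 2-d matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary (values 0/1 only)", call. = FALSE)
  storage.mode(mask) <- "integer"
  lab <- cc_label_8(mask)
  n <- max(lab)
  if (n == 0) {
    pb <- pixel_box()
  } else {
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    # 0-based half-open extents: pixel (row r, col c) covers [c-1, c) x [r-1, r)
    x_min <- tapply(idx[, "col"] - 1L, l, min)
    x_max <- tapply(idx[, "col"], l, max)
    y_min <- tapply(idx[, "row"] - 1L, l, min)
    y_max <- tapply(idx[, "row"], l, max)
    pb <- pixel_box(x_min, y_min, x_max, y_max)
    if (min_area > 0) {
      sizes <- tabulate(l, nbins = n)
      pb <- pb[sizes >= min_area, , drop = FALSE]
      pb <- as_pixel_box(pb)
    }
  }
  if (!normalized) return(pb)
  normalize_boxes(pb, image_width = ncol(mask), image_height = nrow(mask))
}

#' Write detection labels in the standard text format
#'
#' One line per object: `class x_c y_c w h`, space-separated, coordinates
#' normalized to the image size and printed with six decimals (fixed
#' precision so write/read round-trips are bit-stable). An empty record set
#' writes an empty file, which validly encodes "no objects in this tile".
#'
#' @param records a [normalized_box()] data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path) {
  validate_normalized_box(records)
  lines <- if (nrow(records) == 0) character() else
    sprintf("%d %.6f %.6f %.6f %.6f",
            records$class_id, records$x_c, records$y_c, records$w, records$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read detection labels from the standard text format
#'
#' @param path label file written by [write_labels()] (or any detector
#'   emitting the same format).
#' @return a [normalized_box()] data frame (zero rows for an empty file).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(normalized_box())
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(vapply(fields, length, 1L) != 5L)
  if (length(bad))
    stop(sprintf("malformed label line %d in %s: expected 5 fields", bad[1], path),
         call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 5, byrow = TRUE)
  bad <- which(apply(m, 1, function(r) any(!is.finite(r))))
  if (length(bad))
    stop(sprintf("malformed label line %d in %s: non-numeric field", bad[1], path),
         call. = FALSE)
  b <- data.frame(class_id = as.integer(m[, 1]), x_c = m[, 2], y_c = m[, 3],
                  w = m[, 4], h = m[, 5])
  class(b) <- c("normalized_box", "data.frame")
  validate_normalized_box(b)
  b
}

#' Assemble a balanced tile dataset from image/mask pairs
#'
#' Reproduces the dataset-construction procedure used to train the flower
#' detector: every image/mask pair is padded and cut into square tiles, each
#' tile's mask is converted to labels, and a fixed-size subset is drawn at
#' random so that a stated fraction of tiles is completely flower-free
#' (the reference pipeline used 2000 tiles, 30% empty). Tiles are then
#' assigned to train/validation splits.
#'
#' @param pairs list of `list(image =, mask =)` elements; `image` may be
#'   `NULL` when only labels are needed. Masks are binary matrices.
#' @param tile_size tile side in pixels (default 400).
#' @param target_size number of tiles to keep.
#' @param empty_fraction fraction of kept tiles that must contain no
#'   objects; the empty count is `round(empty_fraction * target_size)`.
#' @param seed integer seed; the manifest is deterministic given the seed.
#' @param val_fraction fraction of kept tiles assigned to the validation
#'   split (default 0.2).
#' @param out_dir if non-`NULL`, tile images (PNG) and label files are
#'   written there and the manifest records their paths.
#' @return A data frame (the manifest) with columns `tile_id`, `pair`,
#'   `row`, `col`, `n_objects`, `split`, `image_path`, `label_path`, plus a
#'   `labels` attribute: a list of per-tile [normalized_box()] frames.
#' @export
build_dataset <- function(pairs, tile_size = 400L, target_size,
                          empty_fraction = 0.30, seed = 1L,
                          val_fraction = 0.2, out_dir = NULL) {
  stopifnot(is.list(pairs), length(pairs) > 0, empty_fraction >= 0,
            empty_fraction <= 1, target_size >= 1)
  rows <- list(); labels <- list(); k <- 0L
  for (p in seq_along(pairs)) {
    mask <- pairs[[p]]$mask
    if (is.null(mask)) stop("pair ", p, " has no mask", call. = FALSE)
    d <- image_dims(mask)
    img <- pairs[[p]]$image
    if (!is.null(img)) {
      di <- image_dims(img)
      if (di$width != d$width || di$height != d$height)
        stop("pair ", p, ": image and mask dimensions differ", call. = FALSE)
    }
    grid <- plan_tile_grid(d$width, d$height, tile_size)
    mask_p <- pad_to_grid(mask, grid)
    mtiles <- split_into_tiles(mask_p, grid)
    itiles <- if (is.null(img)) NULL else
      split_into_tiles(pad_to_grid(img, grid), grid)
    for (i in seq_along(mtiles)) {
      k <- k + 1L
      lb <- mask_to_boxes(mtiles[[i]]$image)
      labels[[k]] <- lb
      rows[[k]] <- data.frame(
        tile_id = sprintf("p%03d_r%02d_c%02d", p, mtiles[[i]]$row, mtiles[[i]]$col),
        pair = p, row = mtiles[[i]]$row, col = mtiles[[i]]$col,
        n_objects = nrow(lb), stringsAsFactors = FALSE)
      if (!is.null(itiles)) rows[[k]]$tile_image <- I(list(itiles[[i]]$image))
    }
  }
  manifest <- do.call(rbind, rows)

  n_empty <- as.integer(round(empty_fraction * target_size))
  n_full <- as.integer(target_size) - n_empty
  empties <- which(manifest$n_objects == 0)
  fulls <- which(manifest$n_objects > 0)
  if (length(empties) < n_empty || length(fulls) < n_full)
    stop(sprintf(paste0("cannot draw %d empty and %d non-empty tiles: only %d ",
                        "empty and %d non-empty available"),
                 n_empty, n_full, length(empties), length(fulls)), call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  keep <- c(sample(empties, n_empty), sample(fulls, n_full))
  keep <- sort(keep)
  manifest <- manifest[keep, , drop = FALSE]
  labels <- labels[keep]
  n_val <- as.integer(round(val_fraction * nrow(manifest)))
  split <- rep("train", nrow(manifest))
  split[sample(nrow(manifest), n_val)] <- "val"
  manifest$split <- split

  manifest$image_path <- NA_character_
  manifest$label_path <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      stem <- file.path(out_dir, manifest$tile_id[i])
      manifest$label_path[i] <- paste0(stem, ".txt")
      write_labels(labels[[i]], manifest$label_path[i])
      if (!is.null(manifest$tile_image)) {
        manifest$image_path[i] <- paste0(stem, ".png")
        png::writePNG(clamp01(manifest$tile_image[[i]]), manifest$image_path[i])
      }
    }
  }
  manifest$tile_image <- NULL
  rownames(manifest) <- NULL
  attr(manifest, "labels") <- labels
  manifest
}
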