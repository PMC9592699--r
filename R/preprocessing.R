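# Image preprocessing: CT region-of-interest crop + resize to the 224 x 224
# network input, consecutive-slice channel stacking, whole-slide tiling into
# 224 x 224 patches with blank-tile discard. Coordinates are 0-based and
# half-open throughout.

TILE_SIZE <- 224L

#' Rectangular region of interest
#'
#' @param row_min,row_max,col_min,col_max 0-based half-open pixel bounds
#' @return object of class `roi_spec`
#' @export
roi_spec <- function(row_min, row_max, col_min, col_max) {
  if (row_min < 0 || col_min < 0 || row_max <= row_min || col_max <= col_min)
    stopf("ROI must be a non-empty box with 0-based half-open bounds")
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = "roi_spec")
}

#' Crop a region of interest and resize it to a square network input
#'
#' The box is cropped as given (aspect distortion is allowed) and bilinearly
#' resampled.
#'
#' @param image 2-D matrix or (H, W, C) array
#' @param roi a [roi_spec()]
#' @param size output side length (default 224)
#' @return (size, size) matrix or (size, size, C) array
#' @export
crop_and_resize <- function(image, roi, size = TILE_SIZE) {
  if (!inherits(roi, "roi_spec")) stopf("roi must come from roi_spec()")
  d <- dim(image)
  if (roi$row_max > d[1] || roi$col_max > d[2])
    stopf("ROI [%d,%d) x [%d,%d) exceeds the %d x %d image",
          roi$row_min, roi$row_max, roi$col_min, roi$col_max, d[1], d[2])
  rows <- (roi$row_min + 1L):roi$row_max
  cols <- (roi$col_min + 1L):roi$col_max
  crop <- if (length(d) == 2L) image[rows, cols, drop = FALSE]
          else image[rows, cols, , drop = FALSE]
  out <- bilinear_resize(crop, size, size)
  if (length(d) == 2L) matrix(out, size, size) else array(out, dim = c(size, size, d[3]))
}

#' Stack consecutive slices into 3-channel images
#'
#' Sliding window of width 3 and stride 1: n grayscale slices yield n - 2
#' images whose channels are slices (i, i+1, i+2).
#'
#' @param slices list of equally sized 2-D matrices (n >= 3)
#' @return list of (H, W, 3) arrays
#' @export
stack_slices <- function(slices) {
  n <- length(slices)
  if (n < 3L) stopf("slice stacking needs at least 3 slices, got %d", n)
  d <- dim(slices[[1]])
  lapply(seq_len(n - 2L), function(i) {
    out <- array(0, dim = c(d[1], d[2], 3L))
    for (ch in 0:2) out[, , ch + 1L] <- slices[[i + ch]]
    out
  })
}

#' Tile an image into 224 x 224 patches
#'
#' The grid has K = ceil(X/224) * ceil(Y/224) tiles; tiles extending past the
#' right/bottom edge are zero-padded so every source pixel appears in exactly
#' one tile.
#'
#' @param wsi (Y, X) matrix or (Y, X, C) array
#' @return list with `X`, `Y`, `K`, `coords` (data.frame: `tile`, `row`,
#'   `col`, 0-based pixel offsets `row_off`, `col_off`) and `tiles` (list of
#'   (224, 224, C) arrays)
#' @export
tile_wsi <- function(wsi) {
  d <- dim(wsi)
  if (is.null(d) || any(d[1:2] < 1L)) stopf("empty image")
  if (length(d) == 2L) wsi <- array(wsi, dim = c(d, 1L))
  Yp <- dim(wsi)[1]; Xp <- dim(wsi)[2]; C <- dim(wsi)[3]
  ny <- ceiling(Yp / TILE_SIZE); nx <- ceiling(Xp / TILE_SIZE)
  K <- nx * ny
  tiles <- vector("list", K)
  coords <- data.frame(tile = seq_len(K), row = 0L, col = 0L,
                       row_off = 0L, col_off = 0L)
  t <- 0L
  for (tr in seq_len(ny) - 1L) {
    for (tc in seq_len(nx) - 1L) {
      t <- t + 1L
      r0 <- tr * TILE_SIZE; c0 <- tc * TILE_SIZE
      rows <- (r0 + 1L):min(r0 + TILE_SIZE, Yp)
      cols <- (c0 + 1L):min(c0 + TILE_SIZE, Xp)
      tile <- array(0, dim = c(TILE_SIZE, TILE_SIZE, C))
      tile[seq_along(rows), seq_along(cols), ] <- wsi[rows, cols, , drop = FALSE]
      tiles[[t]] <- tile
      coords$row[t] <- tr; coords$col[t] <- tc
      coords$row_off[t] <- r0; coords$col_off[t] <- c0
    }
  }
  list(X = Xp, Y = Yp, K = K, coords = coords, tiles = tiles)
}

#' Discard blank tiles
#'
#' Keeps tiles whose mean intensity over all channels is below the threshold
#' (blank tissue background is near-white). Idempotent; an empty result is
#' allowed.
#'
#' @param tiles list of arrays with values in \[0, 1\]
#' @param mean_threshold tiles with mean >= this are discarded
#' @return filtered list; attribute `"kept"` carries the logical keep mask
#' @export
discard_blank <- function(tiles, mean_threshold = 0.95) {
  kept <- vapply(tiles, function(tl) mean(tl) < mean_threshold, logical(1))
  structure(tiles[kept], kept = kept)
}

#' Lung-window normalization for real CT input
#'
#' Maps Hounsfield units through the standard lung window (width 1500 HU,
#' level -600 HU) to \[0, 1\]. Not applied to synthetic data, which is
#' already on \[0, 1\].
#'
#' @param hu matrix/array of Hounsfield units
#' @param width,level window width and level in HU
#' @return same shape, values in \[0, 1\]
#' @export
lung_window <- function(hu, width = 1500, level = -600) {
  lo <- level - width / 2
  pmin(pmax((hu - lo) / width, 0), 1)
}

#' Write an image to PNG
#' @param image matrix or (H, W, C) array in \[0, 1\]
#' @param path output file
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Read a PNG image as a numeric array in \[0, 1\]
#' @param path PNG file
#' @return matrix or (H, W, C) array
#' @export
read_image_png <- function(path) png::readPNG(path)
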