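# Image containers, grid geometry, patch resizing and augmentation.

#' Construct an RGB image
#'
#' Images are stored as `height x width x 3` integer arrays of 8-bit sRGB
#' intensities in `[0, 255]`, row 1 at the top of the picture. Grayscale
#' matrices are replicated to three channels.
#'
#' @param pixels numeric array `h x w x 3` (or an `h x w` matrix) with values
#'   in `[0, 255]`.
#' @return an `rgb_image`: integer array with class attribute.
#' @export
rgb_image <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop_validation("pixels must be an h x w x 3 array, got dims [%s]",
                    paste(d, collapse = ", "))
  }
  if (d[1] < 1L || d[2] < 1L) stop_validation("zero-area image")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_validation("pixel values must lie in [0, 255]")
  }
  out <- array(as.integer(round(pixels)), dim = d)
  class(out) <- "rgb_image"
  out
}

#' @rdname rgb_image
#' @param x object to test or query.
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

#' @rdname rgb_image
#' @export
img_height <- function(x) dim(x)[1]

#' @rdname rgb_image
#' @export
img_width <- function(x) dim(x)[2]

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d (w x h)>\n", img_width(x), img_height(x)))
  invisible(x)
}

#' Read an image file
#'
#' Reads a JPEG, PNG or TIFF file into an [rgb_image()]. Grayscale images are
#' replicated to three channels; an alpha channel, if present, is dropped.
#'
#' @param path path to an image file.
#' @return an `rgb_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_validation("image file does not exist: %s", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3] > 3L) {
    a <- a[, , 1:3, drop = FALSE]
  } else if (dim(a)[3] < 3L) {
    a <- array(rep(a[, , 1], 3L), dim = c(dim(a)[1:2], 3L))
  }
  # EBImage stores x (width) as the first dimension in [0, 1] scale.
  a <- aperm(a, c(2L, 1L, 3L))
  rgb_image(pmax(pmin(round(a * 255), 255), 0))
}

#' Write an image as PNG
#'
#' @param image an [rgb_image()].
#' @param path output path (extension selects the format; PNG recommended).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  image <- rgb_image(unclass(image))
  a <- aperm(unclass(image), c(2L, 1L, 3L)) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = EBImage::Color), path)
  invisible(path)
}

new_regions <- function(df, width, height, n_cols, n_rows, overlapping) {
  rownames(df) <- NULL
  structure(df,
            width = width, height = height,
            n_cols = n_cols, n_rows = n_rows,
            overlapping = overlapping,
            class = c("crop_regions", "data.frame"))
}

#' Divide an image into a non-overlapping grid of crop regions
#'
#' Splits a photograph into `n_cols x n_rows` square-ish regions in row-major
#' order (row index varies slowest). Nominal crop dimensions are
#' `round_half_up(width / n_cols)` by `round_half_up(height / n_rows)`; the
#' final column and row are adjusted to end exactly at the image border, so
#' the union of regions covers every pixel. Coordinates are 0-based,
#' half-open: a region occupies pixel columns `[x0, x0 + crop_w)`.
#'
#' For example, a 2592 x 3872 (w x h) photograph divided 8 x 12 yields 96
#' regions of 324 x 323 pixels.
#'
#' @param image an [rgb_image()], or `NULL` when `width`/`height` are given.
#' @param n_cols,n_rows number of grid columns and rows.
#' @param width,height image dimensions (taken from `image` when supplied).
#' @return a `crop_regions` data frame with columns `row_index`, `col_index`,
#'   `x0`, `y0`, `crop_w`, `crop_h`.
#' @export
#' @examples
#' g <- grid_crop(NULL, n_cols = 8, n_rows = 12, width = 2592, height = 3872)
#' unique(g$crop_w[g$col_index < 7])   # 324
grid_crop <- function(image, n_cols, n_rows, width = NULL, height = NULL) {
  if (!is.null(image)) {
    width <- img_width(image)
    height <- img_height(image)
  }
  if (is.null(width) || is.null(height)) {
    stop_validation("supply either an image or width and height")
  }
  if (n_cols < 1L || n_rows < 1L) stop_validation("n_cols and n_rows must be >= 1")
  if (n_cols > width || n_rows > height) {
    stop_validation("grid (%d x %d) finer than image (%d x %d)",
                    n_cols, n_rows, width, height)
  }
  nominal_w <- round_half_up(width / n_cols)
  nominal_h <- round_half_up(height / n_rows)
  axis_starts <- function(n, nominal, extent) {
    x0 <- pmin((seq_len(n) - 1L) * nominal, extent - 1L)
    x1 <- pmin(x0 + nominal, extent)
    x1[n] <- extent                      # last region flush with the border
    x1 <- pmax(x1, x0 + 1L)
    list(x0 = as.integer(x0), w = as.integer(x1 - x0))
  }
  cx <- axis_starts(n_cols, nominal_w, width)
  cy <- axis_starts(n_rows, nominal_h, height)
  idx <- expand.grid(col_index = seq_len(n_cols) - 1L,
                     row_index = seq_len(n_rows) - 1L)
  df <- data.frame(row_index = idx$row_index,
                   col_index = idx$col_index,
                   x0 = cx$x0[idx$col_index + 1L],
                   y0 = cy$x0[idx$row_index + 1L],
                   crop_w = cx$w[idx$col_index + 1L],
                   crop_h = cy$w[idx$row_index + 1L])
  new_regions(df, width, height, n_cols, n_rows, overlapping = FALSE)
}

#' Overlapping grid of crop regions for point mapping
#'
#' Tiles an image with an `n_cols x n_rows` grid of fixed-size crops whose
#' top-left corners are spread evenly from the top-left corner of the image
#' to the position flush with the bottom-right corner:
#' `x0(j) = round(j * (width - crop_w) / (n_cols - 1))` for column
#' `j = 0..n_cols-1`, and likewise for rows. Adjacent crops overlap whenever
#' `n_cols * crop_w > width`, which increases the density of analysed tiles.
#' The default 16 x 24 grid yields 384 regions per photograph.
#'
#' Default crop size matches the whole-tongue training grid (12 x 15), i.e.
#' `crop_w = round(width / 12)` and `crop_h = round(height / 15)`, so that
#' test-time tiles have the same magnification as training patches.
#'
#' @inheritParams grid_crop
#' @param crop_w,crop_h crop dimensions in pixels (defaults above).
#' @return a `crop_regions` data frame, row-major order.
#' @export
overlapping_grid <- function(image, n_cols = 16L, n_rows = 24L,
                             crop_w = NULL, crop_h = NULL,
                             width = NULL, height = NULL) {
  if (!is.null(image)) {
    width <- img_width(image)
    height <- img_height(image)
  }
  if (is.null(width) || is.null(height)) {
    stop_validation("supply either an image or width and height")
  }
  if (n_cols < 1L || n_rows < 1L) stop_validation("n_cols and n_rows must be >= 1")
  if (is.null(crop_w)) crop_w <- round_half_up(width / 12)
  if (is.null(crop_h)) crop_h <- round_half_up(height / 15)
  if (crop_w > width || crop_h > height) {
    stop_validation("crop (%d x %d) larger than image (%d x %d)",
                    crop_w, crop_h, width, height)
  }
  starts <- function(n, crop, extent) {
    if (n == 1L) return(0L)
    as.integer(round_half_up((seq_len(n) - 1L) * (extent - crop) / (n - 1L)))
  }
  xs <- starts(n_cols, crop_w, width)
  ys <- starts(n_rows, crop_h, height)
  idx <- expand.grid(col_index = seq_len(n_cols) - 1L,
                     row_index = seq_len(n_rows) - 1L)
  df <- data.frame(row_index = idx$row_index,
                   col_index = idx$col_index,
                   x0 = xs[idx$col_index + 1L],
                   y0 = ys[idx$row_index + 1L],
                   crop_w = as.integer(crop_w),
                   crop_h = as.integer(crop_h))
  new_regions(df, width, height, n_cols, n_rows, overlapping = TRUE)
}

#' Extract the pixels of one crop region
#'
#' @param image an [rgb_image()].
#' @param region one row of a `crop_regions` data frame (a list or
#'   single-row data frame with `x0`, `y0`, `crop_w`, `crop_h`).
#' @return an `rgb_image` of the region's pixels.
#' @export
crop_pixels <- function(image, region) {
  x0 <- region$x0; y0 <- region$y0
  w <- region$crop_w; h <- region$crop_h
  if (w < 1L || h < 1L) stop_validation("empty crop region")
  if (x0 < 0L || y0 < 0L || x0 + w > img_width(image) ||
      y0 + h > img_height(image)) {
    stop_validation("crop region [%d,%d %dx%d] outside image bounds",
                    x0, y0, w, h)
  }
  rgb_image(unclass(image)[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w), ,
                           drop = FALSE])
}

#' Resize a crop to the classifier input size
#'
#' Bilinear resize to `size x size` pixels (default 96). An input already at
#' the target size is returned unchanged, byte for byte.
#'
#' @param image an [rgb_image()].
#' @param size target side length in pixels.
#' @return a `size x size` `rgb_image`.
#' @export
resize_patch <- function(image, size = 96L) {
  if (img_width(image) == size && img_height(image) == size) return(image)
  a <- aperm(unclass(image), c(2L, 1L, 3L)) / 255
  r <- EBImage::resize(EBImage::Image(a, colormode = EBImage::Color),
                       w = size, h = size)
  out <- aperm(EBImage::imageData(r), c(2L, 1L, 3L))
  rgb_image(pmax(pmin(round(out * 255), 255), 0))
}

flip_h <- function(image) {
  rgb_image(unclass(image)[, rev(seq_len(img_width(image))), , drop = FALSE])
}

flip_v <- function(image) {
  rgb_image(unclass(image)[rev(seq_len(img_height(image))), , , drop = FALSE])
}

rot_90 <- function(image) {
  # 90 degrees clockwise: transpose then reverse columns.
  a <- aperm(unclass(image), c(2L, 1L, 3L))
  rgb_image(a[, rev(seq_len(dim(a)[2])), , drop = FALSE])
}

#' Augment a training patch
#'
#' Returns the four label-preserving variants used to enlarge the training
#' split: the identity, a horizontal flip, a vertical flip and a 90-degree
#' rotation. Augmentation is applied to training patches only; validation and
#' test patches are never augmented.
#'
#' @param patch a square [rgb_image()] (normally 96 x 96).
#' @return named list of four `rgb_image`s:
#'   `identity`, `hflip`, `vflip`, `rot90`.
#' @export
augment <- function(patch) {
  if (img_width(patch) != img_height(patch)) {
    stop_validation("augment() expects a square patch")
  }
  list(identity = patch,
       hflip = flip_h(patch),
       vflip = flip_v(patch),
       rot90 = rot_90(patch))
}

#' Export crop regions as CSV
#'
#' @param regions a `crop_regions` data frame.
#' @param path output CSV path.
#' @param source_id photograph identifier recorded in the file.
#' @return `path`, invisibly.
#' @export
write_regions_csv <- function(regions, path, source_id = NA_character_) {
  df <- data.frame(source_id = source_id, as.data.frame(regions))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
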