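# Point-mapping segmentation: per-tile class predictions on an overlapping
# grid, ground-truth point maps from label masks, and colour-dot rendering.

new_point_map <- function(points, grid, source_id) {
  rownames(points) <- NULL
  structure(list(source_id = source_id, grid = grid, points = points),
            class = "point_map")
}

#' @export
print.point_map <- function(x, ...) {
  cat(sprintf("<point_map %s: %d x %d grid, %d points>\n",
              x$source_id, x$grid$n_cols, x$grid$n_rows, nrow(x$points)))
  invisible(x)
}

grid_meta <- function(regions) {
  list(n_cols = attr(regions, "n_cols"), n_rows = attr(regions, "n_rows"),
       width = attr(regions, "width"), height = attr(regions, "height"),
       crop_w = regions$crop_w[1], crop_h = regions$crop_h[1])
}

point_centers <- function(regions) {
  data.frame(row_index = regions$row_index, col_index = regions$col_index,
             center_x = regions$x0 + regions$crop_w %/% 2L,
             center_y = regions$y0 + regions$crop_h %/% 2L)
}

#' Predict a point map for a photograph
#'
#' Tiles the photograph with an overlapping grid (default 16 x 24 = 384
#' tiles), resizes each tile to the classifier input size, predicts its
#' class, and anchors a point record at the centre of each tile. The result
#' is the point-mapping segmentation of the photograph: one class label and
#' softmax probability vector per grid point.
#'
#' @param image an [rgb_image()] photograph.
#' @param handle a trained `tongue_classifier`.
#' @param n_cols,n_rows overlapping-grid dimensions.
#' @param crop_w,crop_h tile size in pixels (see [overlapping_grid()] for
#'   the defaults tying tile size to training-patch magnification).
#' @param source_id photograph identifier carried on the map.
#' @return a `point_map`: list with `source_id`, `grid` metadata and a
#'   `points` data frame (`row_index`, `col_index`, `center_x`, `center_y`,
#'   `label`, `p_abnormal`, `p_normal`, `p_other`).
#' @export
predict_pointmap <- function(image, handle, n_cols = 16L, n_rows = 24L,
                             crop_w = NULL, crop_h = NULL,
                             source_id = NA_character_) {
  regions <- overlapping_grid(image, n_cols = n_cols, n_rows = n_rows,
                              crop_w = crop_w, crop_h = crop_h)
  patches <- lapply(seq_len(nrow(regions)), function(i) {
    region <- regions[i, ]
    p <- resize_patch(crop_pixels(image, region))
    attr(p, "region") <- region        # provenance, used by oracle backends
    p
  })
  pred <- predict_batch(handle, patches)
  pts <- cbind(point_centers(regions),
               data.frame(label = pred$predicted,
                          p_abnormal = pred$p_abnormal,
                          p_normal = pred$p_normal,
                          p_other = pred$p_other))
  new_point_map(pts, grid_meta(regions), source_id)
}

#' Ground-truth point map from a label mask
#'
#' Places one point per grid cell whose label is the plurality class of the
#' cell's full pixel footprint under the annotation mask (the same support
#' the classifier sees), via [label_region()]. Ground-truth points carry no
#' probabilities.
#'
#' @param mask a [label_mask()].
#' @inheritParams predict_pointmap
#' @return a `point_map` whose points have `label` but `NA` probabilities.
#' @export
ground_truth_pointmap <- function(mask, n_cols = 16L, n_rows = 24L,
                                  crop_w = NULL, crop_h = NULL,
                                  source_id = attr(mask, "source_id")) {
  regions <- overlapping_grid(NULL, n_cols = n_cols, n_rows = n_rows,
                              crop_w = crop_w, crop_h = crop_h,
                              width = ncol(mask), height = nrow(mask))
  labels <- vapply(seq_len(nrow(regions)), function(i) {
    label_region(mask, regions[i, ])
  }, integer(1))
  pts <- cbind(point_centers(regions),
               data.frame(label = labels, p_abnormal = NA_real_,
                          p_normal = NA_real_, p_other = NA_real_))
  new_point_map(pts, grid_meta(regions), source_id)
}

#' Colour conventions for rendered point maps
#'
#' @param abnormal,normal,other dot colours as length-3 RGB vectors in
#'   0..255. Defaults: abnormal blue, normal green, other red.
#' @param radius dot radius in pixels.
#' @return a `render_spec` list.
#' @export
render_spec <- function(abnormal = c(0, 0, 255), normal = c(0, 255, 0),
                        other = c(255, 0, 0), radius = 3L) {
  cols <- rbind(abnormal, normal, other)
  if (nrow(unique(cols)) != 3L) stop_validation("dot colours must be distinct")
  structure(list(colors = cols, radius = as.integer(radius)),
            class = "render_spec")
}

#' Render a point map as a colour-dot overlay
#'
#' Draws one filled dot per grid point on top of the photograph, coloured by
#' predicted class (blue = abnormal, green = normal, red = other by
#' default). Pixels outside the dots are untouched.
#'
#' @param image the source [rgb_image()].
#' @param pmap a `point_map` belonging to that image.
#' @param spec a [render_spec()].
#' @return an [rgb_image()] overlay.
#' @export
render_pointmap <- function(image, pmap, spec = render_spec()) {
  if (pmap$grid$width != img_width(image) ||
      pmap$grid$height != img_height(image)) {
    stop_validation("point map does not belong to this image")
  }
  a <- unclass(image)
  h <- dim(a)[1]; w <- dim(a)[2]
  r <- spec$radius
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  for (i in seq_len(nrow(pmap$points))) {
    p <- pmap$points[i, ]
    ys <- p$center_y + 1L + off$dy
    xs <- p$center_x + 1L + off$dx
    ok <- ys >= 1L & ys <= h & xs >= 1L & xs <= w
    col <- spec$colors[p$label + 1L, ]
    for (ch in 1:3) a[cbind(ys[ok], xs[ok], ch)] <- col[ch]
  }
  rgb_image(a)
}

#' Serialise a point map to CSV
#'
#' Columns: `source_id`, `row_index`, `col_index`, `center_x`, `center_y`,
#' `label`, `p_abnormal`, `p_normal`, `p_other`.
#'
#' @param pmap a `point_map`.
#' @param path output CSV path.
#' @return `path` invisibly; `read_pointmap_csv` returns a `point_map`.
#' @export
write_pointmap_csv <- function(pmap, path) {
  df <- cbind(data.frame(source_id = pmap$source_id,
                         n_cols = pmap$grid$n_cols, n_rows = pmap$grid$n_rows,
                         width = pmap$grid$width, height = pmap$grid$height,
                         crop_w = pmap$grid$crop_w, crop_h = pmap$grid$crop_h),
              pmap$points)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pointmap_csv
#' @export
read_pointmap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  grid <- list(n_cols = df$n_cols[1], n_rows = df$n_rows[1],
               width = df$width[1], height = df$height[1],
               crop_w = df$crop_w[1], crop_h = df$crop_h[1])
  pts <- df[, c("row_index", "col_index", "center_x", "center_y", "label",
                "p_abnormal", "p_normal", "p_other")]
  new_point_map(pts, grid, df$source_id[1])
}
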