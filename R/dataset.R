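# Label masks, patch labelling, dataset assembly and train/valid/test splits.

#' Construct a per-pixel label mask
#'
#' A label mask records the expert annotation of a photograph as one class
#' code per pixel: 0 = abnormal, 1 = normal, 2 = other.
#'
#' @param classes integer matrix `h x w` with values in `{0, 1, 2}`.
#' @param source_id photograph identifier.
#' @return a `label_mask` (integer matrix with attributes).
#' @export
label_mask <- function(classes, source_id = NA_character_) {
  if (!is.matrix(classes)) stop_validation("classes must be a matrix")
  if (anyNA(classes) || !all(classes %in% 0:2)) {
    stop_validation("mask values must be class codes 0, 1 or 2")
  }
  m <- matrix(as.integer(classes), nrow = nrow(classes))
  structure(m, source_id = source_id, class = c("label_mask", class(m)))
}

#' Derive a label mask from a colour-painted annotation image
#'
#' Annotators paint abnormal regions blue and normal tongue mucosa green on
#' top of the photograph; everything left unpainted (non-tongue structures,
#' background) is "other". A pixel is assigned to abnormal/normal when its
#' Euclidean RGB distance to pure blue `(0, 0, 255)` / pure green
#' `(0, 255, 0)` is at most `tolerance`; the default 60 absorbs JPEG
#' compression of the painted annotation. If a pixel falls within tolerance
#' of both references the nearer one wins.
#'
#' @param annotation an [rgb_image()] the same size as the photograph.
#' @param tolerance maximum RGB distance to a reference colour (gray levels).
#' @param source_id photograph identifier carried on the mask.
#' @return a [label_mask()].
#' @export
mask_from_colors <- function(annotation, tolerance = 60, source_id = NA_character_) {
  a <- unclass(annotation)
  d_blue <- sqrt(a[, , 1]^2 + a[, , 2]^2 + (a[, , 3] - 255)^2)
  d_green <- sqrt(a[, , 1]^2 + (a[, , 2] - 255)^2 + a[, , 3]^2)
  m <- matrix(2L, nrow = dim(a)[1], ncol = dim(a)[2])
  m[d_blue <= tolerance & d_blue <= d_green] <- 0L
  m[d_green <= tolerance & d_green < d_blue] <- 1L
  label_mask(m, source_id = source_id)
}

#' Render a label mask as an annotation image
#'
#' Inverse of [mask_from_colors()] at tolerance 0: abnormal pixels become
#' pure blue, normal pixels pure green, other pixels black.
#'
#' @param mask a [label_mask()].
#' @return an [rgb_image()].
#' @export
mask_to_colors <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  a <- array(0, dim = c(h, w, 3L))
  a[, , 3][unclass(mask) == 0L] <- 255   # abnormal -> blue
  a[, , 2][unclass(mask) == 1L] <- 255   # normal -> green
  rgb_image(a)
}

#' Label of a crop region under a mask
#'
#' Returns the plurality class over the region's pixel footprint. Ties are
#' broken by class priority abnormal > normal > other — deliberately
#' conservative toward flagging pathology.
#'
#' @param mask a [label_mask()].
#' @param region a crop region (list with `x0`, `y0`, `crop_w`, `crop_h`).
#' @return integer class code (0, 1 or 2).
#' @export
label_region <- function(mask, region) {
  x0 <- region$x0; y0 <- region$y0
  w <- region$crop_w; h <- region$crop_h
  if (w < 1L || h < 1L) stop_validation("empty region")
  if (x0 < 0L || y0 < 0L || x0 + w > ncol(mask) || y0 + h > nrow(mask)) {
    stop_validation("region outside mask bounds")
  }
  sub <- unclass(mask)[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w)]
  counts <- tabulate(sub + 1L, nbins = 3L)
  # which.max returns the first maximum: class order 0 > 1 > 2 breaks ties.
  which.max(counts) - 1L
}

#' Fraction of a crop's footprint that lies on the tongue
#'
#' Tongue pixels are those labelled abnormal or normal (codes 0 and 1);
#' "other" pixels are off-tongue. Used by [filter_boundary_crops()].
#'
#' @inheritParams label_region
#' @return fraction in `[0, 1]`.
#' @export
crop_tongue_fraction <- function(mask, region) {
  x0 <- region$x0; y0 <- region$y0
  w <- region$crop_w; h <- region$crop_h
  sub <- unclass(mask)[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w)]
  mean(sub != 2L)
}

#' Drop tongue-boundary crops from a region list
#'
#' Crops straddling the tongue outline mix mucosa with background and are
#' excluded from training, mirroring the manual curation of clinical crop
#' datasets: a crop is kept when at least `min_tongue_fraction` of its
#' footprint is tongue tissue, or when it contains no tongue at all (a clean
#' "other" example).
#'
#' @param regions a `crop_regions` data frame.
#' @param mask the photograph's [label_mask()].
#' @param min_tongue_fraction minimum on-tongue footprint fraction (default 0.5).
#' @return the filtered `crop_regions`.
#' @export
filter_boundary_crops <- function(regions, mask, min_tongue_fraction = 0.5) {
  frac <- vapply(seq_len(nrow(regions)), function(i) {
    crop_tongue_fraction(mask, regions[i, ])
  }, numeric(1))
  keep <- frac >= min_tongue_fraction | frac == 0
  regions[keep, , drop = FALSE]
}

#' Assign photograph-grouped stratified splits
#'
#' Partitions patch records into train/validation/test splits such that (a)
#' all patches from one source photograph land in the same split, guarding
#' against train/test leakage of near-identical tissue, and (b) per-class
#' counts approximate the requested fractions as closely as the photograph
#' grouping allows. Assignment is a seeded greedy fill: photographs are
#' visited in seeded random order and each is placed in the split with the
#' largest remaining per-class deficit.
#'
#' @param info data frame with at least columns `label` (class codes 0/1/2)
#'   and `source_id`.
#' @param fractions numeric length-3 vector `(train, valid, test)` summing
#'   to 1; default `c(0.688, 0.154, 0.158)`.
#' @param seed integer seed making the assignment reproducible.
#' @param group_by_source keep all patches of one photograph together
#'   (default). Set `FALSE` for records that are independent draws (e.g.
#'   procedurally generated windows), where the leakage guard is vacuous and
#'   record-level assignment tracks the fractions more closely.
#' @return `info` with a `split` column (`"train"`, `"valid"`, `"test"`).
#' @export
assign_splits <- function(info, fractions = c(0.688, 0.154, 0.158), seed = 1L,
                          group_by_source = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-6) stop_validation("fractions must sum to 1")
  if (length(fractions) != 3L) stop_validation("need (train, valid, test) fractions")
  if (!all(0:2 %in% info$label)) {
    missing <- setdiff(0:2, unique(info$label))
    stop_validation("no records for class(es): %s",
                    paste(class_name(missing), collapse = ", "))
  }
  splits <- c("train", "valid", "test")
  class_totals <- tabulate(info$label + 1L, nbins = 3L)
  target <- outer(class_totals, fractions)        # 3 classes x 3 splits
  cur <- matrix(0, 3L, 3L)
  keys <- if (group_by_source) {
    as.character(info$source_id)
  } else {
    sprintf("record-%d", seq_len(nrow(info)))
  }
  groups <- split(seq_len(nrow(info)), keys)
  ord <- with_seed(seed, sample.int(length(groups)))
  assignment <- character(length(groups))
  names(assignment) <- names(groups)
  for (g in ord) {
    rows <- groups[[g]]
    gc <- tabulate(info$label[rows] + 1L, nbins = 3L)
    # score each split by how much of this group fills a genuine deficit,
    # normalised by split size so small splits are not starved
    score <- vapply(1:3, function(s) {
      deficit <- pmax(target[, s] - cur[, s], 0)
      sum(pmin(gc, deficit)) / fractions[s] -
        1e-9 * sum(pmax(gc - deficit, 0))
    }, numeric(1))
    s <- which.max(score)                         # ties: train > valid > test
    cur[, s] <- cur[, s] + gc
    assignment[names(groups)[g]] <- splits[s]
  }
  info$split <- unname(assignment[keys])
  info
}

#' Per-class, per-split dataset summary
#'
#' Tabulates record counts by class and split in the standard report layout
#' (rows abnormal/normal/other plus a total row; columns total, training,
#' validation, testing).
#'
#' @param info data frame with columns `label` and `split`.
#' @return integer matrix with dimnames.
#' @export
dataset_summary <- function(info) {
  splits <- c("train", "valid", "test")
  m <- matrix(0L, nrow = 4L, ncol = 4L,
              dimnames = list(c(class_names(), "total"),
                              c("total", "training", "validation", "testing")))
  if (nrow(info) > 0) {
    for (si in seq_along(splits)) {
      cnt <- tabulate(info$label[info$split == splits[si]] + 1L, nbins = 3L)
      m[1:3, si + 1L] <- cnt
    }
    m[1:3, 1L] <- rowSums(m[1:3, 2:4, drop = FALSE])
    m[4L, ] <- colSums(m[1:3, , drop = FALSE])
  }
  m
}

#' Split fractions from a dataset summary
#'
#' @param summary a matrix as returned by [dataset_summary()] (total row and
#'   total column present).
#' @return named numeric vector of training/validation/testing fractions, as
#'   percentages.
#' @export
split_fractions <- function(summary) {
  tot <- summary["total", "total"]
  100 * summary["total", c("training", "validation", "testing")] / tot
}

#' Persist and reload a patch dataset manifest
#'
#' A patch dataset on disk is a directory of PNG patches plus a CSV manifest
#' with columns `patch_path`, `label`, `split`, `source_id`, `row`, `col`.
#'
#' @param patches list of 96 x 96 [rgb_image()] patches.
#' @param info data frame with one row per patch (`label`, `split`,
#'   `source_id`, `row`, `col`).
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_patch_dataset <- function(patches, info, dir) {
  stopifnot(length(patches) == nrow(info))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("patch_%05d.png", seq_along(patches)))
  for (i in seq_along(patches)) save_image(patches[[i]], paths[i])
  manifest <- data.frame(patch_path = basename(paths),
                         label = info$label,
                         split = if ("split" %in% names(info)) info$split else NA,
                         source_id = info$source_id,
                         row = if ("row" %in% names(info)) info$row else NA,
                         col = if ("col" %in% names(info)) info$col else NA)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_patch_dataset
#' @export
read_patch_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  patches <- lapply(file.path(dir, manifest$patch_path), load_image)
  list(patches = patches, info = manifest)
}
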