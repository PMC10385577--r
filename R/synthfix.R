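# Procedural generator of tongue-like test imagery with exact per-pixel
# class masks. Textures are parametric and deliberately simple — a dot
# lattice standing in for papillae, grooves for fissures, bright low-chroma
# plaques for keratosis — because the test surface needs controllable class
# separability and pixel-exact masks, not photorealism.

#' Specify a synthetic tongue scene
#'
#' A scene is a dark, textureless background with an elliptical "tongue"
#' carrying normal papillary texture, plus zero or more abnormal patches
#' (lesions) inside the tongue. Every abnormal patch has a shape and an
#' abnormality type drawn from [abnormality_tags()]; four types have
#' dedicated textures (`papillary_atrophy`, `fissures`,
#' `hyperkeratotic_change`, `tongue_coating`) and the remaining tags render
#' with a generic lesion texture.
#'
#' Lesion shapes: `"ellipse"` (fields `cx`, `cy`, `rx`, `ry`),
#' `"halfplane"` (field `side`: left/right/top/bottom half of the tongue),
#' `"whole"` (the entire tongue), `"checker"` (field `cell`: alternating
#' `cell`-pixel squares of the tongue).
#'
#' @param width,height scene dimensions in pixels.
#' @param seed integer seed; every texture draws from a stream derived
#'   from it, so scenes are bitwise reproducible.
#' @param tongue list `(cx, cy, rx, ry)` of the tongue ellipse, or `NULL`
#'   for a background-only scene. Default: a centred ellipse spanning about
#'   80% of the frame.
#' @param lesions list of abnormal patches (see above), each a list with a
#'   `shape`, shape fields and a `type`.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(width = 480L, height = 640L, seed = 1L,
                       tongue = list(cx = width / 2, cy = height / 2,
                                     rx = 0.40 * width, ry = 0.44 * height),
                       lesions = list()) {
  for (les in lesions) {
    if (is.null(les$shape)) stop_validation("each lesion needs a shape")
    if (!is.null(les$type) && !les$type %in% abnormality_tags()) {
      stop_validation("unknown abnormality type: %s", les$type)
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 seed = as.integer(seed), tongue = tongue, lesions = lesions),
            class = "scene_spec")
}

scene_coords <- function(spec) {
  x <- matrix(rep(seq_len(spec$width) - 1L, each = spec$height),
              nrow = spec$height)
  y <- matrix(rep(seq_len(spec$height) - 1L, times = spec$width),
              nrow = spec$height)
  list(x = x, y = y)
}

inside_ellipse <- function(co, e) {
  ((co$x - e$cx) / e$rx)^2 + ((co$y - e$cy) / e$ry)^2 <= 1
}

lesion_region <- function(les, co, tongue_in, spec) {
  reg <- switch(les$shape,
    ellipse = inside_ellipse(co, les),
    halfplane = switch(les$side,
      left = co$x < spec$tongue$cx, right = co$x >= spec$tongue$cx,
      top = co$y < spec$tongue$cy, bottom = co$y >= spec$tongue$cy,
      stop_validation("unknown halfplane side: %s", les$side)),
    whole = tongue_in,
    checker = ((co$x %/% les$cell) + (co$y %/% les$cell)) %% 2 == 0,
    stop_validation("unknown lesion shape: %s", les$shape))
  if (les$shape == "ellipse" && any(reg & !tongue_in)) {
    stop_validation("abnormal patch extends outside the tongue ellipse")
  }
  reg & tongue_in
}

# fill three channels of `img` with base colour + gaussian noise on `region`
paint_noise <- function(img, region, base, noise_sd, seed) {
  n <- sum(region)
  if (n == 0L) return(img)
  with_seed(seed, {
    for (ch in 1:3) {
      v <- base[ch] + stats::rnorm(n, sd = noise_sd)
      img[, , ch][region] <- pmax(pmin(v, 255), 0)
    }
  })
  img
}

# quasi-regular bright-dot lattice (papillae surrogate) on `region`
paint_papillae <- function(img, region, spec, seed,
                           spacing = 7, radius = 2, color = c(238, 206, 200)) {
  h <- spec$height; w <- spec$width
  gx <- seq(spacing / 2, w - 1, by = spacing)
  gy <- seq(spacing / 2, h - 1, by = spacing)
  centers <- expand.grid(x = gx, y = gy)
  with_seed(seed, {
    centers$x <- centers$x + stats::runif(nrow(centers), -2, 2)
    centers$y <- centers$y + stats::runif(nrow(centers), -2, 2)
  })
  off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  for (i in seq_len(nrow(centers))) {
    cx <- round(centers$x[i]); cy <- round(centers$y[i])
    ys <- cy + 1L + off$dy; xs <- cx + 1L + off$dx
    ok <- ys >= 1L & ys <= h & xs >= 1L & xs <= w
    ys <- ys[ok]; xs <- xs[ok]
    on <- region[cbind(ys, xs)]        # never paint across a mask boundary
    if (!any(on)) next
    for (ch in 1:3) img[cbind(ys[on], xs[on], ch)] <- color[ch]
  }
  img
}

# dark curvilinear grooves (fissure surrogate) on `region`
paint_grooves <- function(img, region, spec, seed,
                          pitch = 18, amp = 4, wavelength = 57,
                          half_width = 1, color = c(58, 24, 30)) {
  h <- spec$height; w <- spec$width
  xcols <- seq_len(w) - 1L
  with_seed(seed, {
    for (y0 in seq(pitch / 2, h - 1, by = pitch)) {
      phase <- stats::runif(1, 0, 2 * pi)
      yc <- y0 + amp * sin(2 * pi * xcols / wavelength + phase)
      for (dy in -half_width:half_width) {
        ys <- round(yc) + dy + 1L
        ok <- ys >= 1L & ys <= h
        idx <- cbind(ys[ok], which(ok))
        on <- region[idx]
        if (!any(on)) next
        for (ch in 1:3) img[cbind(idx[on, 1L], idx[on, 2L], ch)] <- color[ch]
      }
    }
  })
  img
}

lesion_palette <- list(
  papillary_atrophy = list(base = c(198, 72, 82), sd = 2),
  hyperkeratotic_change = list(base = c(228, 223, 214), sd = 4),
  tongue_coating = list(base = c(216, 212, 185), sd = 10),
  fissures = list(base = c(205, 120, 125), sd = 4),
  generic = list(base = c(182, 138, 170), sd = 6)
)

#' Generate a synthetic tongue scene
#'
#' Renders the image and its exact per-pixel class mask: `other` outside the
#' tongue ellipse, `abnormal` exactly on the abnormal patches, `normal`
#' elsewhere inside the ellipse. Texture boundaries coincide with mask class
#' boundaries by construction. Deterministic: the same spec yields
#' bitwise-identical output.
#'
#' @param spec a [scene_spec()].
#' @return a `synthetic_sample`: list with `image` ([rgb_image()]), `mask`
#'   ([label_mask()]) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  co <- scene_coords(spec)
  tongue_in <- if (is.null(spec$tongue)) {
    matrix(FALSE, spec$height, spec$width)
  } else inside_ellipse(co, spec$tongue)

  mask <- matrix(2L, spec$height, spec$width)
  mask[tongue_in] <- 1L
  lesion_regions <- lapply(spec$lesions, lesion_region, co = co,
                           tongue_in = tongue_in, spec = spec)
  for (reg in lesion_regions) mask[reg] <- 0L

  img <- array(0, dim = c(spec$height, spec$width, 3L))
  img <- paint_noise(img, !tongue_in, c(32, 28, 34), 3,
                     derive_seed(spec$seed, "background"))
  normal_in <- mask == 1L
  img <- paint_noise(img, normal_in, c(208, 122, 128), 5,
                     derive_seed(spec$seed, "normal-base"))
  img <- paint_papillae(img, normal_in, spec,
                        derive_seed(spec$seed, "papillae"))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    reg <- lesion_regions[[i]]
    type <- les$type %||% "generic"
    pal <- lesion_palette[[type]] %||% lesion_palette$generic
    img <- paint_noise(img, reg, pal$base, pal$sd,
                       derive_seed(spec$seed, paste0("lesion-", i)))
    if (identical(type, "fissures")) {
      img <- paint_grooves(img, reg, spec,
                           derive_seed(spec$seed, paste0("grooves-", i)))
    }
  }
  structure(list(image = rgb_image(img),
                 mask = label_mask(mask, source_id = sprintf("scene-%d", spec$seed)),
                 spec = spec),
            class = "synthetic_sample")
}

# top-left positions from which a `win`-sized window lies entirely in cells
# of `mask` equal to `value`; returns a 2-column matrix (x0, y0), 0-based
pure_window_positions <- function(mask, value, win) {
  ok <- unclass(mask) == value
  cs <- apply(ok, 2, cumsum)                 # column-wise prefix sums
  cs <- rbind(0, cs)
  colblock <- cs[(win + 1L):nrow(cs), , drop = FALSE] -
    cs[1:(nrow(cs) - win), , drop = FALSE]   # rows of win-tall all-ok runs
  full <- colblock == win
  rs <- t(apply(full, 1, cumsum))
  rs <- cbind(0, rs)
  block <- rs[, (win + 1L):ncol(rs), drop = FALSE] -
    rs[, 1:(ncol(rs) - win), drop = FALSE]
  pos <- which(block == win, arr.ind = TRUE)
  cbind(x0 = pos[, 2L] - 1L, y0 = pos[, 1L] - 1L)
}

#' Generate a balanced labelled patch benchmark
#'
#' Samples `n_per_class` patches of each class from a small set of generated
#' scenes: normal patches from an all-normal tongue, abnormal patches from
#' scenes carrying one large lesion of each dedicated texture type (cycled),
#' and "other" patches from off-tongue background. Windows of `window_size`
#' pixels are cut where the mask is pure, resized to `patch_size`, and the
#' label of every patch is re-derived from the mask via [label_region()].
#'
#' `window_size` controls magnification: 96 (default) samples patches at
#' native scale; `round(width / 12)` matches the tile size used for
#' whole-tongue point mapping.
#'
#' @param seed integer seed.
#' @param n_per_class patches per class.
#' @param window_size sampled window side length in pixels.
#' @param patch_size output patch side length (classifier input size).
#' @return list with `patches` (list of [rgb_image()]) and `info` (data
#'   frame: `label`, `source_id`, `type`, `row`, `col`).
#' @export
generate_patch_benchmark <- function(seed = 7L, n_per_class = 100L,
                                     window_size = 96L, patch_size = 96L) {
  stopifnot(n_per_class >= 1L)
  types <- c("papillary_atrophy", "fissures", "hyperkeratotic_change",
             "tongue_coating")
  normal_scene <- generate_scene(scene_spec(seed = derive_seed(seed, "normal")))
  lesion_scenes <- lapply(types, function(tp) {
    generate_scene(scene_spec(
      seed = derive_seed(seed, tp),
      lesions = list(list(shape = "ellipse", cx = 240, cy = 320,
                          rx = 150, ry = 210, type = tp))))
  })
  names(lesion_scenes) <- types

  sample_windows <- function(sample_obj, value, n, key) {
    pos <- pure_window_positions(sample_obj$mask, value, window_size)
    if (nrow(pos) < 1L) stop_validation("no pure windows available")
    idx <- with_seed(derive_seed(seed, key),
                     sample.int(nrow(pos), n, replace = nrow(pos) < n))
    lapply(idx, function(i) {
      region <- list(x0 = pos[i, 1L], y0 = pos[i, 2L],
                     crop_w = window_size, crop_h = window_size)
      list(region = region,
           patch = resize_patch(crop_pixels(sample_obj$image, region),
                                patch_size),
           label = label_region(sample_obj$mask, region),
           source_id = attr(sample_obj$mask, "source_id"))
    })
  }

  normal <- sample_windows(normal_scene, 1L, n_per_class, "win-normal")
  other <- sample_windows(normal_scene, 2L, n_per_class, "win-other")
  per_type <- diff(round(seq(0, n_per_class, length.out = length(types) + 1)))
  abnormal <- unlist(lapply(seq_along(types), function(i) {
    sample_windows(lesion_scenes[[i]], 0L, per_type[i],
                   paste0("win-", types[i]))
  }), recursive = FALSE)
  recs <- c(abnormal, normal, other)
  type_tags <- c(rep(types, per_type), rep(NA_character_, 2L * n_per_class))
  info <- data.frame(
    label = vapply(recs, `[[`, integer(1), "label"),
    source_id = vapply(recs, `[[`, character(1), "source_id"),
    type = type_tags,
    row = vapply(recs, function(r) r$region$y0, numeric(1)),
    col = vapply(recs, function(r) r$region$x0, numeric(1)))
  list(patches = lapply(recs, `[[`, "patch"), info = info)
}

#' Named suite of degenerate end-to-end fixtures
#'
#' Five fixed-seed scenes exercising the boundary cases of the pipeline:
#' `all_normal` (healthy tongue), `all_abnormal` (atrophy over the entire
#' tongue), `half_half` (left half of the tongue abnormal), `checkerboard`
#' (alternating abnormal squares), and `no_tongue` (background only).
#'
#' @param seed base seed for the suite.
#' @return named list of `synthetic_sample`s.
#' @export
fixture_suite <- function(seed = 42L) {
  list(
    all_normal = generate_scene(scene_spec(seed = derive_seed(seed, "all_normal"))),
    all_abnormal = generate_scene(scene_spec(
      seed = derive_seed(seed, "all_abnormal"),
      lesions = list(list(shape = "whole", type = "papillary_atrophy")))),
    half_half = generate_scene(scene_spec(
      seed = derive_seed(seed, "half_half"),
      lesions = list(list(shape = "halfplane", side = "left",
                          type = "papillary_atrophy")))),
    checkerboard = generate_scene(scene_spec(
      seed = derive_seed(seed, "checkerboard"),
      lesions = list(list(shape = "checker", cell = 64,
                          type = "hyperkeratotic_change")))),
    no_tongue = generate_scene(scene_spec(seed = derive_seed(seed, "no_tongue"),
                                          tongue = NULL))
  )
}

#' Write a synthetic sample to disk
#'
#' Emits `<stem>_image.png`, `<stem>_mask.png` (canonical blue/green colour
#' coding) and `<stem>_spec.json`.
#'
#' @param sample a `synthetic_sample`.
#' @param stem output path stem.
#' @return character vector of the three paths, invisibly.
#' @export
write_synthetic_sample <- function(sample, stem) {
  paths <- paste0(stem, c("_image.png", "_mask.png", "_spec.json"))
  save_image(sample$image, paths[1])
  save_image(mask_to_colors(sample$mask), paths[2])
  jsonlite::write_json(unclass(sample$spec), paths[3],
                       digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
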