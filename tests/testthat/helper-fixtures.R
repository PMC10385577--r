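# Shared fixtures, built once per test run.

# mask pixel values without identity attributes, for exact comparisons
mask_values <- function(m) {
  x <- unclass(m)
  attributes(x) <- list(dim = dim(x))
  x
}

solid_image <- function(h, w, rgb = c(120, 60, 200)) {
  a <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) a[, , ch] <- rgb[ch]
  rgb_image(a)
}

checker_image <- function(h, w, cell = 8, lo = 0, hi = 255) {
  x <- matrix(rep(seq_len(w) - 1L, each = h), nrow = h)
  y <- matrix(rep(seq_len(h) - 1L, times = w), nrow = h)
  g <- ifelse(((x %/% cell) + (y %/% cell)) %% 2 == 0, lo, hi)
  rgb_image(array(rep(g, 3), dim = c(h, w, 3)))
}

random_image <- function(h, w, seed = 1) {
  set.seed(seed)
  rgb_image(array(sample.int(256, h * w * 3, replace = TRUE) - 1L,
                  dim = c(h, w, 3)))
}

random_mask <- function(h, w, seed = 1) {
  set.seed(seed)
  label_mask(matrix(sample(0:2, h * w, replace = TRUE), nrow = h))
}

# Build a point map directly from a labels matrix (rows = grid rows).
make_pointmap <- function(labels, probs = NULL, width = 160, height = 240,
                          source_id = "synthetic") {
  n_rows <- nrow(labels); n_cols <- ncol(labels)
  regions <- overlapping_grid(NULL, n_cols = n_cols, n_rows = n_rows,
                              crop_w = 16, crop_h = 16,
                              width = width, height = height)
  pts <- data.frame(row_index = regions$row_index,
                    col_index = regions$col_index,
                    center_x = regions$x0 + 8L, center_y = regions$y0 + 8L,
                    label = as.integer(t(labels)[cbind(
                      regions$col_index + 1L, regions$row_index + 1L)]))
  if (is.null(probs)) {
    pts$p_abnormal <- NA_real_; pts$p_normal <- NA_real_; pts$p_other <- NA_real_
  } else {
    onehot <- diag(3)[pts$label + 1L, , drop = FALSE]
    pts$p_abnormal <- onehot[, 1] * probs + (1 - probs) / 2 * (1 - onehot[, 1])
    pts$p_normal <- onehot[, 2] * probs + (1 - probs) / 2 * (1 - onehot[, 2])
    pts$p_other <- onehot[, 3] * probs + (1 - probs) / 2 * (1 - onehot[, 3])
  }
  tonguemap:::new_point_map(pts,
    list(n_cols = n_cols, n_rows = n_rows, width = width, height = height,
         crop_w = 16L, crop_h = 16L), source_id)
}

# Brute-force oracle for seg_counts: materialise the two point sets and
# intersect them as (row, col) keys.
seg_counts_oracle <- function(gt, pred, class) {
  key <- function(pm, k) {
    sel <- pm$points$label == k
    paste(pm$points$row_index[sel], pm$points$col_index[sel])
  }
  kg <- key(gt, class); kp <- key(pred, class)
  G <- length(kg); P <- length(kp); I <- length(intersect(kg, kp))
  S <- length(union(kg, kp))
  list(G = G, P = P, I = I, S = S,
       iou = if (S == 0) 1 else I / S)
}

.cache <- new.env()

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

get_benchmark <- function(n_per_class = 200, seed = 7) {
  cached(sprintf("bench-%d-%d", n_per_class, seed),
         generate_patch_benchmark(seed = seed, n_per_class = n_per_class))
}

get_fixtures <- function() cached("fixtures", fixture_suite(42))

# Baseline trained at the point-mapping tile magnification (window 40 px,
# matching round(480 / 12) map tiles on the default scene size).
train_on_map_scale <- function() {
  cached("baseline-map-scale", {
    b <- generate_patch_benchmark(seed = 7, n_per_class = 60, window_size = 40)
    train_classifier(b$patches, b$info$label,
                     classifier_config("texture-baseline"))
  })
}

get_baseline <- function() {
  cached("baseline", {
    b <- get_benchmark()
    train_classifier(b$patches, b$info$label,
                     classifier_config("texture-baseline"))
  })
}
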