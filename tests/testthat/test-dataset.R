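test_that("mask_from_colors maps painted colours to classes", {
  green <- solid_image(10, 10, c(0, 255, 0))
  expect_true(all(unclass(mask_from_colors(green)) == 1L))

  unpainted <- solid_image(10, 10, c(90, 90, 90))
  expect_true(all(unclass(mask_from_colors(unpainted)) == 2L))

  half <- unclass(solid_image(10, 10, c(0, 0, 0)))
  half[, 1:4, 3] <- 255                  # blue block, 40 pixels per row
  half[, 5:10, 2] <- 255                 # green block
  m <- mask_from_colors(rgb_image(half))
  expect_equal(sum(unclass(m) == 0L), 40)
  expect_equal(sum(unclass(m) == 1L), 60)

  # painted colours survive mild perturbation within tolerance
  perturbed <- unclass(solid_image(5, 5, c(20, 30, 230)))
  expect_true(all(unclass(mask_from_colors(rgb_image(perturbed))) == 0L))
})

test_that("mask render / parse round-trips exactly at tolerance zero", {
  m <- random_mask(17, 23, seed = 3)
  back <- mask_from_colors(mask_to_colors(m), tolerance = 0)
  expect_identical(unclass(back), unclass(m))
})

test_that("label_region applies the plurality rule with abnormal-first ties", {
  m <- label_mask(matrix(0L, 20, 20))
  expect_equal(label_region(m, list(x0 = 2, y0 = 2, crop_w = 5, crop_h = 5)), 0L)

  # 60% normal, 40% other
  mm <- matrix(2L, 10, 10)
  mm[1:6, ] <- 1L
  expect_equal(label_region(label_mask(mm),
                            list(x0 = 0, y0 = 0, crop_w = 10, crop_h = 10)), 1L)

  # exact 50/50 abnormal/normal resolves to abnormal
  tie <- matrix(c(rep(0L, 50), rep(1L, 50)), 10, 10)
  expect_equal(label_region(label_mask(tie),
                            list(x0 = 0, y0 = 0, crop_w = 10, crop_h = 10)), 0L)

  expect_error(label_region(m, list(x0 = 18, y0 = 0, crop_w = 5, crop_h = 5)),
               "bounds")
})

test_that("label_region matches a pixel-histogram oracle on random regions", {
  m <- random_mask(40, 50, seed = 8)
  set.seed(21)
  for (i in 1:50) {
    w <- sample.int(20, 1); h <- sample.int(20, 1)
    x0 <- sample.int(50 - w, 1) - 1L; y0 <- sample.int(40 - h, 1) - 1L
    region <- list(x0 = x0, y0 = y0, crop_w = w, crop_h = h)
    sub <- unclass(m)[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)]
    counts <- c(sum(sub == 0), sum(sub == 1), sum(sub == 2))
    oracle <- (which(counts == max(counts))[1]) - 1L
    expect_identical(label_region(m, region), oracle)
  }
})

test_that("splits partition records, conserve classes and respect grouping", {
  set.seed(2)
  info <- data.frame(
    label = sample(0:2, 600, replace = TRUE),
    source_id = rep(sprintf("photo-%02d", 1:60), each = 10))
  out <- assign_splits(info, seed = 5)
  expect_true(all(out$split %in% c("train", "valid", "test")))
  expect_equal(nrow(out), nrow(info))
  # leakage guard: one photograph, one split
  per_photo <- tapply(out$split, out$source_id, function(s) length(unique(s)))
  expect_true(all(per_photo == 1))
  # class totals conserved
  expect_equal(tabulate(out$label + 1, 3), tabulate(info$label + 1, 3))
  # determinism
  expect_identical(assign_splits(info, seed = 5)$split, out$split)
  # distinct seeds may permute photographs
  expect_equal(sort(unique(assign_splits(info, seed = 6)$split)),
               sort(unique(out$split)))

  all_train <- assign_splits(info, fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))

  expect_error(assign_splits(data.frame(label = c(0, 1), source_id = "a")),
               "class")
})

test_that("record-level splits track the requested fractions closely", {
  set.seed(9)
  info <- data.frame(label = rep(0:2, times = c(322, 281, 175)),
                     source_id = "one-scene")
  out <- assign_splits(info, fractions = c(0.688, 0.154, 0.158), seed = 3,
                       group_by_source = FALSE)
  summ <- dataset_summary(out)
  target <- 778 * c(0.688, 0.154, 0.158)
  expect_true(all(abs(summ["total", 2:4] - target) <= 3))
})

test_that("dataset_summary books counts consistently", {
  info <- data.frame(label = rep(0:2, each = 100), source_id = "s",
                     split = rep(c("train", "valid", "test"),
                                 times = c(70, 15, 15)))
  summ <- dataset_summary(info)
  expect_equal(unname(summ["total", "total"]), 300L)
  expect_equal(unname(summ[1:3, "total"]), rep(100L, 3))
  expect_equal(sum(summ[1:3, 2:4]), 300)

  empty <- dataset_summary(data.frame(label = integer(0), split = character(0)))
  expect_true(all(empty == 0L))
})

test_that("the reference split table gives the published fractions", {
  rc <- reference_dataset_counts()
  fr <- split_fractions(rc)
  expect_equal(unname(fr["validation"]), 15.4, tolerance = 0.005)
  expect_equal(unname(fr["testing"]), 15.8, tolerance = 0.005)
  # training: 5358/7782 = 68.85%, printed as 68.8 (truncated)
  expect_equal(floor(10 * fr[["training"]]) / 10, 68.8)
})

test_that("boundary crops are filtered by tongue footprint", {
  mm <- matrix(2L, 40, 40)
  mm[, 1:20] <- 1L                        # left half tongue
  m <- label_mask(mm)
  regions <- grid_crop(NULL, 4, 4, width = 40, height = 40)
  kept <- filter_boundary_crops(regions, m, min_tongue_fraction = 0.6)
  fracs <- vapply(seq_len(nrow(kept)), function(i)
    crop_tongue_fraction(m, kept[i, ]), numeric(1))
  expect_true(all(fracs >= 0.6 | fracs == 0))
  expect_lt(nrow(kept), nrow(regions) + 1)
})

test_that("patch datasets persist to PNG + manifest and reload", {
  patches <- lapply(1:6, function(i) random_image(96, 96, seed = i))
  info <- data.frame(label = rep(0:2, 2), split = "train",
                     source_id = "scene-1", row = 0, col = 0:5)
  dir <- withr::local_tempdir()
  write_patch_dataset(patches, info, dir)
  back <- read_patch_dataset(dir)
  expect_equal(length(back$patches), 6)
  expect_equal(back$info$label, info$label)
  expect_identical(unclass(back$patches[[3]]), unclass(patches[[3]]))
})
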