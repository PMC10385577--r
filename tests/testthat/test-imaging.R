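test_that("images round-trip through PNG and grayscale is replicated", {
  img <- random_image(40, 30, seed = 11)
  path <- withr::local_tempfile(fileext = ".png")
  save_image(img, path)
  back <- load_image(path)
  expect_identical(dim(back), dim(img))
  expect_identical(unclass(back), unclass(img))

  gray <- rgb_image(matrix(seq(0, 255, length.out = 12), nrow = 3))
  expect_identical(gray[, , 1], gray[, , 3])

  jpg <- withr::local_tempfile(fileext = ".jpg")
  save_image(img, jpg)
  expect_identical(dim(load_image(jpg)), dim(img))

  expect_error(load_image("no/such/file.png"), "exist")
  expect_error(rgb_image(array(0, dim = c(0, 5, 3))), "zero-area")
})

test_that("grid_crop reproduces the whole-tongue crop geometry", {
  g <- grid_crop(NULL, n_cols = 8, n_rows = 12, width = 2592, height = 3872)
  expect_equal(nrow(g), 96)
  expect_true(all(g$crop_w == 324))
  # nominal height 323 = round-half-up(3872 / 12); the floor value 322 would
  # leave uncovered rows
  expect_true(all(g$crop_h[g$row_index < 11] == 323))
  expect_equal(round_half_up(3872 / 12), 323)
  # last row clipped at the border
  last <- g[g$row_index == 11, ][1, ]
  expect_equal(last$y0 + last$crop_h, 3872)
})

test_that("grid_crop degenerate and clipped cases cover every pixel", {
  img <- solid_image(96, 96)
  g1 <- grid_crop(img, 1, 1)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$x0, g1$y0, g1$crop_w, g1$crop_h), c(0, 0, 96, 96))

  g <- grid_crop(NULL, 3, 3, width = 10, height = 10)
  expect_equal(nrow(g), 9)
  expect_true(all(g$crop_w[g$col_index < 2] == 3))
  painted <- matrix(0L, 10, 10)
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    painted[(r$y0 + 1):(r$y0 + r$crop_h), (r$x0 + 1):(r$x0 + r$crop_w)] <-
      painted[(r$y0 + 1):(r$y0 + r$crop_h), (r$x0 + 1):(r$x0 + r$crop_w)] + 1L
  }
  expect_true(all(painted >= 1L))
  expect_error(grid_crop(NULL, 0, 3, width = 10, height = 10), "must be >= 1")
})

test_that("grid_crop coverage and count hold across random geometries", {
  set.seed(4)
  for (rep in 1:25) {
    w <- sample(5:80, 1); h <- sample(5:80, 1)
    nc <- sample.int(min(w, 9), 1); nr <- sample.int(min(h, 9), 1)
    g <- grid_crop(NULL, nc, nr, width = w, height = h)
    expect_equal(nrow(g), nc * nr)
    painted <- matrix(0L, h, w)
    for (i in seq_len(nrow(g))) {
      r <- g[i, ]
      painted[(r$y0 + 1):(r$y0 + r$crop_h), (r$x0 + 1):(r$x0 + r$crop_w)] <- 1L
    }
    expect_true(all(painted == 1L),
                label = sprintf("full coverage for %dx%d grid %dx%d", w, h, nc, nr))
  }
})

test_that("overlapping_grid spreads crops from corner to corner", {
  og <- overlapping_grid(NULL, 16, 24, width = 2592, height = 3872)
  expect_equal(nrow(og), 384)
  expect_equal(og$x0[1], 0)
  expect_equal(og$y0[1], 0)
  last <- og[nrow(og), ]
  expect_equal(last$x0 + last$crop_w, 2592)
  expect_equal(last$y0 + last$crop_h, 3872)

  g <- overlapping_grid(NULL, n_cols = 4, n_rows = 2, crop_w = 40, crop_h = 40,
                        width = 100, height = 50)
  expect_equal(sort(unique(g$x0)), c(0, 20, 40, 60))

  # zero-stride degenerate: crop equals the image, all regions identical
  z <- overlapping_grid(NULL, 3, 3, crop_w = 30, crop_h = 20,
                        width = 30, height = 20)
  expect_true(all(z$x0 == 0) && all(z$y0 == 0))
  expect_error(overlapping_grid(NULL, 2, 2, crop_w = 50, crop_h = 10,
                                width = 40, height = 40), "larger")
})

test_that("resize_patch is exact at the target size and preserves constancy", {
  p <- random_image(96, 96, seed = 5)
  expect_identical(resize_patch(p), p)

  solid <- solid_image(323, 324, c(37, 200, 90))
  r <- resize_patch(solid)
  expect_equal(dim(r), c(96L, 96L, 3L))
  expect_true(all(abs(r[, , 1] - 37) <= 1))
  expect_true(all(abs(r[, , 2] - 200) <= 1))

  cb <- checker_image(192, 192, cell = 24)
  rc <- resize_patch(cb)
  expect_lt(abs(mean(rc) - mean(unclass(cb))), 1)
})

test_that("augmentation is label-preserving, involutive and size-preserving", {
  p <- random_image(96, 96, seed = 9)
  aug <- augment(p)
  expect_named(aug, c("identity", "hflip", "vflip", "rot90"))
  expect_identical(aug$identity, p)
  expect_identical(tonguemap:::flip_h(aug$hflip), p)
  expect_identical(tonguemap:::flip_v(aug$vflip), p)
  r <- p
  for (i in 1:4) r <- tonguemap:::rot_90(r)
  expect_identical(r, p)
  expect_true(all(vapply(aug, function(a) all(dim(a) == dim(p)), logical(1))))

  # a dataset of N training patches grows to 4N
  patches <- lapply(1:5, function(i) random_image(96, 96, seed = i))
  info <- data.frame(label = c(0, 1, 2, 0, 1), source_id = "s",
                     split = "train")
  grown <- tonguemap:::augment_training_split(patches, info)
  expect_equal(length(grown$patches), 20)
  expect_equal(grown$info$label, rep(info$label, each = 4))
})
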