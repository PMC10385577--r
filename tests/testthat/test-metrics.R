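test_that("class metrics reproduce the published per-class table", {
  cm <- reference_confusion("vgg16")
  rep3 <- classification_report(cm, digits = 3)
  ab <- rep3[rep3$class == "abnormal", ]
  expect_equal(ab$precision, 0.935)
  expect_equal(ab$recall, 0.986)
  expect_equal(ab$f1, 0.960)
  expect_equal(ab$accuracy, 0.967)
  expect_equal(rep3$f1[rep3$class == "normal"], 0.968)
  expect_equal(rep3$precision[rep3$class == "other"], 0.988)
})

test_that("class metrics handle perfect and hand-computed matrices", {
  perfect <- as_confusion_matrix(diag(c(5, 7, 9)))
  r <- classification_report(perfect)
  expect_true(all(unlist(r[, 2:5]) == 1))

  cm <- as_confusion_matrix(rbind(c(2, 1, 0), c(0, 3, 0), c(0, 0, 4)))
  m <- class_metrics(cm, 0)
  expect_equal(m$precision, 1.0)
  expect_equal(m$recall, 2 / 3)

  empty_col <- as_confusion_matrix(rbind(c(0, 2, 0), c(0, 3, 0), c(0, 0, 4)))
  m0 <- class_metrics(empty_col, 0)
  expect_equal(m0$precision, 0)
  expect_true(attr(m0, "undefined")["precision"])
})

test_that("one-vs-rest accuracy matches a binary relabelling oracle", {
  set.seed(31)
  for (rep in 1:20) {
    actual <- sample(0:2, 60, replace = TRUE)
    predicted <- sample(0:2, 60, replace = TRUE)
    cm <- confusion_matrix(actual, predicted)
    for (k in 0:2) {
      m <- class_metrics(cm, k)
      bin_acc <- mean((actual == k) == (predicted == k))
      expect_equal(m$accuracy, bin_acc)
      expect_equal(unname(m$counts["tp"] + m$counts["fp"] + m$counts["fn"] +
                            m$counts["tn"]), 60)
    }
    expect_equal(sum(vapply(0:2, function(k) class_metrics(cm, k)$counts["tp"],
                            numeric(1))), sum(diag(cm)))
  }
})

test_that("roc_auc is the pairwise rank probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # {pos: 0.9, 0.8; neg: 0.7, 0.85}: 3 of 4 pairs ordered correctly
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(c(0.2, 0.3), c(1, 1)), "positive and negative")
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.4)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("seg_counts follows the G/P/I/S arithmetic", {
  set.seed(5)
  labs <- matrix(sample(0:2, 24, replace = TRUE), 6, 4)
  gt <- make_pointmap(labs)
  pred_same <- make_pointmap(labs)
  sc <- seg_counts(gt, pred_same, 1)
  expect_equal(sc$I, sc$G)
  expect_equal(sc$iou, 1)

  disjoint <- make_pointmap(matrix(2L, 6, 4))
  sc0 <- seg_counts(gt, disjoint, 0)
  expect_equal(sc0$I, 0)
  expect_equal(sc0$iou, 0)

  # constructed counts G=10, P=8, I=6
  g <- matrix(2L, 5, 4); g[1:10] <- 0L
  p <- matrix(2L, 5, 4); p[5:12] <- 0L
  sc2 <- seg_counts(make_pointmap(g), make_pointmap(p), 0)
  expect_equal(sc2[c("G", "P", "I", "S", "tp", "fp", "fn")],
               list(G = 10, P = 8, I = 6, S = 12, tp = 6, fp = 2, fn = 4))
  expect_equal(sc2$iou, 0.5)
  im <- image_seg_metrics(make_pointmap(g), make_pointmap(p))
  expect_equal(im$precision[1], 0.75)
  expect_equal(im$recall[1], 0.6)

  expect_error(seg_counts(make_pointmap(g),
                          make_pointmap(matrix(0L, 4, 4)), 0), "grids")
})

test_that("seg_counts matches the set-intersection oracle with IoU bounds", {
  set.seed(77)
  for (rep in 1:200) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    gt <- make_pointmap(matrix(sample(0:2, nr * nc, TRUE), nr, nc))
    pred <- make_pointmap(matrix(sample(0:2, nr * nc, TRUE), nr, nc))
    for (k in 0:2) {
      sc <- seg_counts(gt, pred, k)
      oc <- seg_counts_oracle(gt, pred, k)
      expect_equal(sc[c("G", "P", "I", "S")], oc[c("G", "P", "I", "S")])
      expect_equal(sc$iou, oc$iou)
      expect_true(sc$I <= min(sc$G, sc$P))
      expect_true(sc$S >= max(sc$G, sc$P))
      im <- image_seg_metrics(gt, pred)
      expect_lte(im$iou[k + 1], im$precision[k + 1] + 1e-12)
      expect_lte(im$iou[k + 1], im$recall[k + 1] + 1e-12)
    }
  }
})

test_that("image_confidence averages softmax over predicted points", {
  labs <- matrix(c(0L, 0L, 1L, 2L), 2, 2)
  pm <- make_pointmap(labs, probs = 0.9)
  expect_equal(image_confidence(pm, 0), 0.9)
  # no points of a class -> 0
  pm_no <- make_pointmap(matrix(1L, 2, 2), probs = 0.8)
  expect_equal(image_confidence(pm_no, 0), 0)
  # manual two-point average
  pm2 <- make_pointmap(matrix(c(0L, 0L, 1L, 1L), 2, 2), probs = 0.8)
  pm2$points$p_abnormal[pm2$points$label == 0] <- c(0.8, 0.6)
  expect_equal(image_confidence(pm2, 0), 0.7)
  # "all" mode averages every grid point
  expect_equal(image_confidence(pm2, 0, mode = "all"),
               mean(pm2$points$p_abnormal))
})

test_that("macro averages use the unweighted mean-of-class-means convention", {
  ref <- reference_pointmap_metrics()
  expect_equal(round_half_up(mean(ref$iou), 3), 0.705)
  expect_equal(round_half_up(mean(ref$precision), 3), 0.739)
  expect_equal(round_half_up(mean(ref$f1), 3), 0.760)

  one <- list(data.frame(class = class_names(),
                         precision = c(0.5, 0.6, 0.7),
                         recall = c(0.4, 0.5, 0.6),
                         f1 = c(0.44, 0.54, 0.64), iou = c(0.3, 0.4, 0.5)))
  m1 <- macro_average(one)
  expect_equal(m1$precision[1:3], c(0.5, 0.6, 0.7))
  two <- c(one, list(transform(one[[1]], iou = c(0.5, 0.6, 0.7))))
  m2 <- macro_average(two)
  expect_equal(m2$iou[1:3], c(0.4, 0.5, 0.6))
  expect_equal(m2$iou[4], mean(c(0.4, 0.5, 0.6)))
})

test_that("voc_ap follows the ranked precision-envelope rule", {
  all_good <- voc_ap(c(0.9, 0.8, 0.7), c(TRUE, TRUE, TRUE), n_gt = 3)
  expect_equal(all_good$ap, 1.0)
  expect_equal(voc_ap(c(0.9, 0.5), c(FALSE, FALSE), n_gt = 2)$ap, 0.0)

  # correct / incorrect / correct over 3 instances:
  # precision (1, 1/2, 2/3), recall (1/3, 1/3, 2/3)
  # envelope (1, 2/3, 2/3) -> AP = 1/3 * 1 + 1/3 * 2/3 = 5/9
  out <- voc_ap(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), n_gt = 3)
  expect_equal(out$ap, 5 / 9)
  # brute-force envelope integration over a dense recall grid
  grid <- seq(1e-6, 2 / 3, length.out = 20000)
  brute <- mean(vapply(grid, function(r) {
    max(out$curve$precision[out$curve$recall >= r - 1e-12])
  }, numeric(1))) * (2 / 3)
  expect_equal(out$ap, brute, tolerance = 1e-3)

  # documented tie rule: equal confidences keep their input order
  t1 <- voc_ap(c(0.8, 0.8, 0.8), c(TRUE, FALSE, TRUE), n_gt = 3)
  expect_equal(t1$curve$tp, c(TRUE, FALSE, TRUE))
  # and detections with distinct confidences are unaffected by input order
  sh <- c(3, 1, 2)
  t2 <- voc_ap(c(0.9, 0.8, 0.7)[sh], c(TRUE, FALSE, TRUE)[sh], n_gt = 3)
  expect_equal(t2$ap, out$ap)

  # 11-point interpolation on the same example
  out11 <- voc_ap(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), n_gt = 3,
                  interpolation = "11-point")
  # interpolated precision: 1 for r in {0,.1,.2,.3}; 2/3 for {.4,.5,.6}; 0 above
  expect_equal(out11$ap, (4 * 1 + 3 * 2 / 3) / 11)
})

test_that("confusion matrices round-trip through CSV", {
  cm <- reference_confusion("xception")
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, path)
  expect_identical(unclass(read_confusion_csv(path)), unclass(cm))
})
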