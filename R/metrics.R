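# Evaluation mathematics: confusion-matrix metrics, ROC/AUC, point-count
# segmentation metrics (G/P/I/S and IoU), macro averages and PASCAL-VOC
# average precision.

#' Build a 3 x 3 confusion matrix
#'
#' Rows are actual classes, columns predicted classes, both in the canonical
#' order abnormal, normal, other.
#'
#' @param actual,predicted integer class codes (0/1/2).
#' @return 3 x 3 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  m <- matrix(0L, 3L, 3L, dimnames = list(actual = class_names(),
                                          predicted = class_names()))
  for (i in seq_along(actual)) {
    m[actual[i] + 1L, predicted[i] + 1L] <- m[actual[i] + 1L, predicted[i] + 1L] + 1L
  }
  as_confusion_matrix(m)
}

#' @rdname confusion_matrix
#' @param m a 3 x 3 matrix of counts (rows actual, columns predicted).
#' @export
as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) stop_validation("confusion matrix must be 3 x 3")
  if (any(m < 0) || anyNA(m)) stop_validation("counts must be non-negative")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(actual = class_names(), predicted = class_names())
  class(m) <- c("confusion_matrix", "matrix", "array")
  m
}

#' @export
print.confusion_matrix <- function(x, ...) {
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(y, ...)
  invisible(x)
}

#' One-vs-rest counts for a single class
#'
#' Binarises the 3-class confusion matrix for one class: `TP` is the
#' diagonal entry, `FP` the rest of the class's predicted column, `FN` the
#' rest of its actual row, and `TN` everything else.
#'
#' @param cm a [confusion_matrix()].
#' @param class integer class code or class name.
#' @return named numeric vector `c(tp, fp, fn, tn)`.
#' @export
ovr_counts <- function(cm, class) {
  k <- class_code(class) + 1L
  tp <- cm[k, k]
  fp <- sum(cm[, k]) - tp
  fn <- sum(cm[k, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_ratio <- function(num, den, vacuous = 0) {
  if (den == 0) structure(vacuous, undefined = TRUE) else num / den
}

#' Per-class classification metrics
#'
#' One-vs-rest precision, recall, F1-score and accuracy derived from a
#' 3-class confusion matrix:
#' \deqn{precision = TP/(TP+FP),\quad recall = TP/(TP+FN)}
#' \deqn{F1 = 2 \cdot precision \cdot recall / (precision + recall)}
#' \deqn{accuracy = (TP+TN)/(TP+TN+FP+FN)}
#' A metric with a zero denominator is reported as 0 and flagged via an
#' `undefined` attribute on the returned list.
#'
#' @inheritParams ovr_counts
#' @return list with `precision`, `recall`, `f1`, `accuracy` and the raw
#'   `counts`.
#' @export
class_metrics <- function(cm, class) {
  if (sum(cm) == 0) stop_validation("empty confusion matrix")
  ct <- ovr_counts(cm, class)
  precision <- safe_ratio(ct["tp"], ct["tp"] + ct["fp"])
  recall <- safe_ratio(ct["tp"], ct["tp"] + ct["fn"])
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else structure(0, undefined = TRUE)
  accuracy <- (ct["tp"] + ct["tn"]) / sum(ct)
  undef <- c(precision = isTRUE(attr(precision, "undefined")),
             recall = isTRUE(attr(recall, "undefined")),
             f1 = isTRUE(attr(f1, "undefined")))
  out <- list(precision = as.numeric(precision), recall = as.numeric(recall),
              f1 = as.numeric(f1), accuracy = as.numeric(accuracy),
              counts = ct)
  attr(out, "undefined") <- undef
  out
}

#' Classification report for all three classes
#'
#' @param cm a [confusion_matrix()].
#' @param digits decimal places for the report (round half-up); `NA` leaves
#'   values unrounded.
#' @return data frame with one row per class: precision, recall, f1,
#'   accuracy.
#' @export
classification_report <- function(cm, digits = NA) {
  rows <- lapply(0:2, function(k) {
    m <- class_metrics(cm, k)
    data.frame(class = class_name(k), precision = m$precision,
               recall = m$recall, f1 = m$f1, accuracy = m$accuracy)
  })
  out <- do.call(rbind, rows)
  if (!is.na(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  out
}

#' Overall (micro) accuracy of a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @return trace / total.
#' @export
overall_accuracy <- function(cm) {
  sum(diag(cm)) / sum(cm)
}

#' One-vs-rest ROC AUC via the rank statistic
#'
#' Computes the area under the ROC curve as the normalised Mann-Whitney
#' statistic: the probability that a random positive example scores higher
#' than a random negative one, with ties counting one half.
#'
#' @param scores numeric scores (e.g. the softmax probability of the class).
#' @param positive logical (or 0/1) vector marking positive examples.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop_validation("roc_auc needs both positive and negative examples")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

check_same_grid <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  same <- identical(ga$n_cols, gb$n_cols) && identical(ga$n_rows, gb$n_rows) &&
    identical(ga$width, gb$width) && identical(ga$height, gb$height)
  if (!same) stop_validation("point maps use different grids")
}

#' Point-count segmentation quantities for one class
#'
#' For a ground-truth and a predicted point map on the same grid, counts the
#' grid points of the class in the ground truth (`G`), in the prediction
#' (`P`) and in both (`I`, the intersection), and derives the union
#' `S = G + P - I`, `TP = I`, `FP = P - I`, `FN = G - I` and
#' `IoU = I / S`. When the class occurs in neither map (`S = 0`) the IoU is
#' reported as 1 (vacuously perfect agreement) and flagged.
#'
#' @param gt,pred `point_map`s on the same grid.
#' @param class integer class code or name.
#' @return list with `G`, `P`, `I`, `S`, `tp`, `fp`, `fn`, `iou`.
#' @export
seg_counts <- function(gt, pred, class) {
  check_same_grid(gt, pred)
  k <- class_code(class)
  in_gt <- gt$points$label == k
  in_pred <- pred$points$label == k
  G <- sum(in_gt); P <- sum(in_pred); I <- sum(in_gt & in_pred)
  S <- G + P - I
  iou <- safe_ratio(I, S, vacuous = 1)
  list(G = G, P = P, I = I, S = S,
       tp = I, fp = P - I, fn = G - I, iou = as.numeric(iou))
}

#' Mean softmax confidence of a class on one point map
#'
#' The confidence of a class on an image is the mean softmax probability of
#' that class over the points *predicted as* that class (0 when the class is
#' never predicted). Setting `mode = "all"` averages over every grid point
#' instead.
#'
#' @param pmap a predicted `point_map` (with probabilities).
#' @param class integer class code or name.
#' @param mode `"predicted"` (default) or `"all"`.
#' @return mean probability in `[0, 1]`.
#' @export
image_confidence <- function(pmap, class, mode = c("predicted", "all")) {
  mode <- match.arg(mode)
  k <- class_code(class)
  probs <- pmap$points[[c("p_abnormal", "p_normal", "p_other")[k + 1L]]]
  if (all(is.na(probs))) stop_validation("point map carries no probabilities")
  if (mode == "all") return(mean(probs))
  sel <- pmap$points$label == k
  if (!any(sel)) return(0)
  mean(probs[sel])
}

#' Per-image segmentation metrics for all classes
#'
#' Combines [seg_counts()] per class with precision `I/P`, recall `I/G`, F1
#' and IoU for one test image, plus (when the predicted map carries
#' probabilities) the per-class confidence from [image_confidence()].
#' Zero-denominator conventions: a ratio 0/0 with no ground truth and no
#' prediction is vacuously 1; `P = 0` with `G > 0` gives precision 0, and
#' symmetrically for recall.
#'
#' @inheritParams seg_counts
#' @param confidence_mode passed to [image_confidence()].
#' @return data frame with one row per class: `class`, `G`, `P`, `I`, `S`,
#'   `precision`, `recall`, `f1`, `iou`, `confidence`.
#' @export
image_seg_metrics <- function(gt, pred, confidence_mode = "predicted") {
  has_probs <- !all(is.na(pred$points$p_abnormal))
  rows <- lapply(0:2, function(k) {
    sc <- seg_counts(gt, pred, k)
    precision <- if (sc$P == 0) (if (sc$G == 0) 1 else 0) else sc$I / sc$P
    recall <- if (sc$G == 0) (if (sc$P == 0) 1 else 0) else sc$I / sc$G
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    conf <- if (has_probs) image_confidence(pred, k, confidence_mode) else NA_real_
    data.frame(class = class_name(k), G = sc$G, P = sc$P, I = sc$I, S = sc$S,
               precision = precision, recall = recall, f1 = f1, iou = sc$iou,
               confidence = conf)
  })
  do.call(rbind, rows)
}

#' Macro averages over a set of test images
#'
#' Unweighted arithmetic mean of per-image, per-class precision, recall, F1
#' and IoU, plus a `"mean"` row holding the unweighted mean of the three
#' class means — the layout of a point-mapping evaluation report.
#'
#' @param per_image list of data frames from [image_seg_metrics()].
#' @param digits decimal places (half-up) for the report; `NA` = unrounded.
#' @return data frame with rows abnormal, normal, other, mean.
#' @export
macro_average <- function(per_image, digits = NA) {
  stopifnot(length(per_image) >= 1L)
  all_rows <- do.call(rbind, per_image)
  cols <- c("precision", "recall", "f1", "iou")
  per_class <- lapply(class_names(), function(cn) {
    sub <- all_rows[all_rows$class == cn, cols, drop = FALSE]
    data.frame(class = cn, t(colMeans(sub)))
  })
  out <- do.call(rbind, per_class)
  out <- rbind(out, data.frame(class = "mean",
                               t(colMeans(out[, cols]))))
  if (!is.na(digits)) out[cols] <- lapply(out[cols], round_half_up, digits)
  rownames(out) <- NULL
  out
}

#' PASCAL-VOC average precision
#'
#' Ranks detections by descending confidence (ties keep their input order)
#' and accumulates precision and recall, treating each test image's class
#' region as one ground-truth instance; a detection is correct when its
#' point-count IoU with the ground truth is at least the threshold (0.5).
#' AP is the area under the precision envelope:
#'
#' * `"all-point"` (default) — precision made monotone non-increasing from
#'   the right, integrated across every recall step (VOC 2010+);
#' * `"11-point"` — mean of the interpolated precision at recalls
#'   0, 0.1, ..., 1 (VOC 2007).
#'
#' @param confidence numeric per-detection confidences.
#' @param correct logical: detection IoU >= threshold.
#' @param n_gt number of ground-truth instances (images where the class is
#'   present).
#' @param interpolation `"all-point"` or `"11-point"`.
#' @return list with `ap`, and the ranked `curve` data frame
#'   (`confidence`, `tp`, `precision`, `recall`).
#' @export
voc_ap <- function(confidence, correct, n_gt,
                   interpolation = c("all-point", "11-point")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(confidence) == length(correct))
  if (length(confidence) == 0L || n_gt == 0L) {
    return(list(ap = 0, curve = data.frame(confidence = numeric(0),
                                           tp = logical(0),
                                           precision = numeric(0),
                                           recall = numeric(0))))
  }
  ord <- order(-confidence)            # stable: equal confidences keep order
  correct <- as.logical(correct)[ord]
  confidence <- confidence[ord]
  tp_cum <- cumsum(correct)
  precision <- tp_cum / seq_along(correct)
  recall <- tp_cum / n_gt
  curve <- data.frame(confidence = confidence, tp = correct,
                      precision = precision, recall = recall)
  if (interpolation == "11-point") {
    ap <- mean(vapply(seq(0, 1, by = 0.1), function(r) {
      p <- precision[recall >= r - 1e-12]
      if (length(p) == 0L) 0 else max(p)
    }, numeric(1)))
  } else {
    env <- rev(cummax(rev(precision)))
    r_prev <- c(0, recall[-length(recall)])
    ap <- sum((recall - r_prev) * env)
  }
  list(ap = ap, curve = curve)
}

#' Average precision per class over a set of point maps
#'
#' Convenience wrapper assembling the VOC bookkeeping from matched
#' ground-truth / predicted point-map pairs: one detection per (image,
#' class) with the class predicted somewhere (`P > 0`), confidence =
#' [image_confidence()], correct when the image's class IoU >= `threshold`;
#' one ground-truth instance per image where the class is present (`G > 0`).
#'
#' @param gt_maps,pred_maps lists of matched `point_map`s.
#' @param threshold IoU correctness threshold (0.5).
#' @param interpolation passed to [voc_ap()].
#' @param confidence_mode passed to [image_confidence()].
#' @return data frame with one row per class: `class`, `n_gt`,
#'   `n_detections`, `ap`.
#' @export
voc_ap_by_class <- function(gt_maps, pred_maps, threshold = 0.5,
                            interpolation = "all-point",
                            confidence_mode = "predicted") {
  stopifnot(length(gt_maps) == length(pred_maps))
  rows <- lapply(0:2, function(k) {
    conf <- numeric(0); corr <- logical(0); n_gt <- 0L
    for (i in seq_along(gt_maps)) {
      sc <- seg_counts(gt_maps[[i]], pred_maps[[i]], k)
      if (sc$G > 0) n_gt <- n_gt + 1L
      if (sc$P > 0) {
        conf <- c(conf, image_confidence(pred_maps[[i]], k, confidence_mode))
        corr <- c(corr, sc$G > 0 && sc$iou >= threshold)
      }
    }
    ap <- voc_ap(conf, corr, n_gt, interpolation)$ap
    data.frame(class = class_name(k), n_gt = n_gt,
               n_detections = length(conf), ap = ap)
  })
  do.call(rbind, rows)
}

#' Read / write confusion matrices as CSV
#'
#' The CSV layout matches the report convention: a 3 x 3 block of counts
#' with actual classes as rows and predicted classes as columns.
#'
#' @param path CSV path.
#' @return `read_confusion_csv` returns a [confusion_matrix()].
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  as_confusion_matrix(as.matrix(df))
}

#' @rdname read_confusion_csv
#' @param cm a [confusion_matrix()].
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
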