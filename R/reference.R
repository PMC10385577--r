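# Bundled reference tables from a published VGG16/ResNet-50/Xception
# tongue-crop classification experiment. They let the evaluation stack be
# exercised (and its arithmetic verified) without access to the clinical
# photographs or a trained model.

ref_path <- function(file) {
  system.file("extdata", file, package = "tonguemap", mustWork = TRUE)
}

#' Reference confusion matrices
#'
#' 3 x 3 test-set confusion matrices (rows actual, columns predicted) of
#' three convolutional backbones evaluated on 1228 labelled tongue crop
#' images. Feeding these into [classification_report()] reproduces the
#' published per-class precision/recall/F1/accuracy figures.
#'
#' @param model `"vgg16"`, `"resnet50"` or `"xception"`.
#' @return a [confusion_matrix()].
#' @export
reference_confusion <- function(model = c("vgg16", "resnet50", "xception")) {
  model <- match.arg(model)
  read_confusion_csv(ref_path(sprintf("confusion_%s.csv", model)))
}

#' Reference dataset split counts
#'
#' Per-class counts of a 7782-crop dataset divided into training,
#' validation and test splits (68.8% / 15.4% / 15.8%).
#'
#' @return matrix in the [dataset_summary()] layout (classes + total rows;
#'   total/training/validation/testing columns).
#' @export
reference_dataset_counts <- function() {
  df <- utils::read.csv(ref_path("dataset_counts.csv"), row.names = 1)
  m <- as.matrix(df)
  m <- rbind(m, total = colSums(m))
  storage.mode(m) <- "integer"
  m
}

#' Reference point-mapping segmentation metrics
#'
#' Per-class macro-averaged precision, recall, F1, IoU and VOC average
#' precision from a point-mapping evaluation of 80 whole-tongue
#' photographs. Used to verify the macro-average ("mean value" row)
#' convention of [macro_average()].
#'
#' @return data frame with rows abnormal, normal, other.
#' @export
reference_pointmap_metrics <- function() {
  utils::read.csv(ref_path("pointmap_reference_metrics.csv"),
                  stringsAsFactors = FALSE)
}
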