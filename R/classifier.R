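# Pluggable 3-class patch classifier: configuration, texture-feature
# baseline, small trainable CNN (see cnn.R) and external-oracle adapter.

#' Classifier configuration
#'
#' Captures the training recipe for the patch classifier: stochastic
#' gradient descent with learning rate 0.005 and momentum 0.9, categorical
#' cross-entropy loss, a dropout rate of 0.5 before the softmax head, and 50
#' epochs by default. Batch size (32) and the absence of early stopping are
#' package defaults. Backbones:
#'
#' * `"texture-baseline"` — a deterministic nearest-centroid classifier on
#'   hand-crafted texture features ([texture_baseline_features()]); its
#'   closed-form "training" serves as a fast, fully reproducible oracle.
#' * `"small-cnn"` — a compact convolutional network trained from scratch on
#'   the CPU ([train_small_cnn()]).
#' * `"external"` — wraps a caller-supplied `predict_fn(patch) -> probs`,
#'   e.g. a ground-truth oracle or an externally trained model.
#'
#' @param backbone one of `"texture-baseline"`, `"small-cnn"`, `"external"`.
#' @param learning_rate,momentum SGD hyper-parameters.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param epochs number of training epochs (>= 1).
#' @param batch_size minibatch size for the CNN backend.
#' @param seed integer seed controlling initialisation, shuffling, dropout.
#' @param input_size patch side length in pixels (96).
#' @param predict_fn function for the external backend.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(backbone = c("texture-baseline", "small-cnn",
                                           "external"),
                              learning_rate = 0.005, momentum = 0.9,
                              dropout_rate = 0.5, epochs = 50L,
                              batch_size = 32L, seed = 1L,
                              input_size = 96L, predict_fn = NULL) {
  backbone <- match.arg(backbone)
  if (learning_rate <= 0) stop_validation("learning_rate must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_validation("dropout_rate must be in [0, 1)")
  }
  if (epochs < 1L) stop_validation("epochs must be >= 1")
  if (backbone == "external" && !is.function(predict_fn)) {
    stop_validation("external backbone requires a predict_fn")
  }
  structure(list(backbone = backbone, learning_rate = learning_rate,
                 momentum = momentum, dropout_rate = dropout_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), input_size = as.integer(input_size),
                 n_classes = 3L, predict_fn = predict_fn),
            class = "classifier_config")
}

#' Texture features of a 96 x 96 patch
#'
#' A fixed-length, deterministic feature vector designed so that the texture
#' classes of the synthetic generator (and, roughly, real tongue textures)
#' are separable without any learning beyond per-class centroids:
#'
#' 1. `mean_r`, `mean_g`, `mean_b` — mean channel intensities (0..1 scale);
#' 2. `contrast` — local-contrast energy, the mean squared deviation of the
#'    gray image from its 3 x 3 neighbourhood mean;
#' 3. `blobs` — bright-dot density: connected components of at least 3
#'    pixels that stand out from the 3 x 3-smoothed image by more than
#'    `max(0.5 sd, 0.02)`, per 1000 pixels (papillae show up as a dot
#'    lattice; the absolute offset keeps pixel noise from counting);
#' 4. `edges` — edge density: fraction of interior pixels whose central
#'    difference gradient magnitude exceeds 0.05.
#'
#' All statistics are invariant under horizontal/vertical flips and
#' 90-degree rotation, so predictions do not depend on the augmentation tag.
#'
#' @param patch a 96 x 96 [rgb_image()].
#' @return named numeric vector of length 6.
#' @export
texture_baseline_features <- function(patch) {
  a <- unclass(patch) / 255
  gray <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  h <- nrow(gray); w <- ncol(gray)

  means <- c(mean_r = mean(a[, , 1]), mean_g = mean(a[, , 2]),
             mean_b = mean(a[, , 3]))

  # 3x3 box mean on the interior (symmetric under flips and rotation)
  if (h >= 3 && w >= 3) {
    ci <- 2:(h - 1); cj <- 2:(w - 1)
    nb <- (gray[ci - 1, cj - 1] + gray[ci - 1, cj] + gray[ci - 1, cj + 1] +
           gray[ci,     cj - 1] + gray[ci,     cj] + gray[ci,     cj + 1] +
           gray[ci + 1, cj - 1] + gray[ci + 1, cj] + gray[ci + 1, cj + 1]) / 9
    contrast <- mean((gray[ci, cj] - nb)^2)
    gx <- (gray[ci, cj + 1] - gray[ci, cj - 1]) / 2
    gy <- (gray[ci + 1, cj] - gray[ci - 1, cj]) / 2
    edges <- mean(sqrt(gx^2 + gy^2) > 0.05)
  } else {
    contrast <- 0; edges <- 0
  }

  s <- stats::sd(gray)
  if (is.na(s) || s < 1e-8 || h < 3 || w < 3) {
    blobs <- 0
  } else {
    sm <- nb                                 # 3x3 box mean of the interior
    bw <- sm > mean(sm) + max(0.5 * stats::sd(sm), 0.02)
    lab <- EBImage::bwlabel(EBImage::Image(t(bw)))
    sizes <- tabulate(lab[lab > 0])
    blobs <- 1000 * sum(sizes >= 3) / (h * w)
  }

  c(means, contrast = 100 * contrast, blobs = blobs, edges = edges)
}

#' Train a patch classifier
#'
#' Dispatches on `config$backbone`. Preconditions: at least one training
#' record per class. Training is deterministic given the seed, the data and
#' the backend. Returns a `tongue_classifier` handle usable with
#' [predict_patch()] / [predict_batch()], carrying a `report` data frame of
#' per-epoch training/validation loss and accuracy.
#'
#' @param patches list of 96 x 96 [rgb_image()] training patches.
#' @param labels integer class codes (0/1/2), one per patch.
#' @param config a [classifier_config()].
#' @param valid_patches,valid_labels optional validation set.
#' @return a `tongue_classifier` handle.
#' @export
train_classifier <- function(patches, labels, config = classifier_config(),
                             valid_patches = NULL, valid_labels = NULL) {
  labels <- as.integer(labels)
  if (config$backbone != "external") {
    present <- tabulate(labels + 1L, nbins = 3L)
    if (any(present == 0L)) {
      stop_validation("training split lacks class(es): %s",
                      paste(class_name(which(present == 0L) - 1L), collapse = ", "))
    }
  }
  model <- switch(config$backbone,
    "texture-baseline" = fit_texture_baseline(patches, labels),
    "small-cnn" = train_small_cnn(patches, labels, config,
                                  valid_patches, valid_labels),
    "external" = list(predict_fn = config$predict_fn, report = NULL))
  report <- model$report
  if (is.null(report)) {
    acc <- NA_real_
    if (config$backbone == "texture-baseline") {
      acc <- mean(vapply(seq_along(patches), function(i) {
        predict_with_model(config$backbone, model, patches[[i]])$predicted ==
          labels[i]
      }, logical(1)))
    }
    report <- data.frame(epoch = 1L, train_loss = NA_real_, train_acc = acc,
                         valid_loss = NA_real_, valid_acc = NA_real_)
  }
  structure(list(backbone = config$backbone, model = model,
                 config = config, report = report),
            class = "tongue_classifier")
}

fit_texture_baseline <- function(patches, labels) {
  feats <- t(vapply(patches, texture_baseline_features, numeric(6)))
  sds <- apply(feats, 2, stats::sd)
  sds[!is.finite(sds) | sds < 1e-8] <- 1
  centroids <- t(vapply(0:2, function(k) {
    colMeans(feats[labels == k, , drop = FALSE])
  }, numeric(6)))
  list(centroids = centroids, scale = sds, report = NULL)
}

predict_with_model <- function(backbone, model, patch) {
  if (backbone == "texture-baseline") {
    f <- texture_baseline_features(patch)
    z <- sweep(sweep(model$centroids, 2, f, "-"), 2, model$scale, "/")
    score <- -0.5 * rowSums(z^2)
    p <- exp(score - max(score))
    p <- p / sum(p)
  } else if (backbone == "small-cnn") {
    p <- cnn_predict_probs(model, list(patch))[1, ]
  } else {
    p <- model$predict_fn(patch)
    if (length(p) == 1L) {            # a bare class code: one-hot it
      pv <- rep(0, 3); pv[as.integer(p) + 1L] <- 1; p <- pv
    }
    if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) {
      stop_validation("external predict_fn must return a probability vector")
    }
  }
  list(probs = as.numeric(p), predicted = which.max(p) - 1L)
}

#' Predict the class of a patch
#'
#' Returns the softmax probabilities over (abnormal, normal, other) and the
#' arg-max class; probability ties are broken by class priority
#' abnormal > normal > other.
#'
#' @param handle a trained `tongue_classifier`.
#' @param patch a 96 x 96 [rgb_image()].
#' @return list with `probs` (length-3 numeric summing to 1) and `predicted`
#'   (integer class code).
#' @export
predict_patch <- function(handle, patch) {
  if (!inherits(handle, "tongue_classifier")) {
    stop_validation("predict_patch() needs a trained tongue_classifier")
  }
  predict_with_model(handle$backbone, handle$model, patch)
}

#' @rdname predict_patch
#' @param patches list of patches.
#' @return for `predict_batch`, a data frame with columns `p_abnormal`,
#'   `p_normal`, `p_other`, `predicted` (one row per patch).
#' @export
predict_batch <- function(handle, patches) {
  if (!inherits(handle, "tongue_classifier")) {
    stop_validation("predict_batch() needs a trained tongue_classifier")
  }
  if (handle$backbone == "small-cnn") {
    p <- cnn_predict_probs(handle$model, patches)
    pred <- max.col(p, ties.method = "first") - 1L
    return(data.frame(p_abnormal = p[, 1], p_normal = p[, 2],
                      p_other = p[, 3], predicted = pred))
  }
  res <- lapply(patches, function(x) predict_patch(handle, x))
  p <- do.call(rbind, lapply(res, `[[`, "probs"))
  data.frame(p_abnormal = p[, 1], p_normal = p[, 2], p_other = p[, 3],
             predicted = vapply(res, `[[`, integer(1), "predicted"))
}

#' Ground-truth oracle classifier
#'
#' An `external`-backend classifier that, for a patch cut from a known
#' photograph, returns the ground-truth label of the patch's source region
#' with probability 1. Used in end-to-end tests: with this oracle the
#' predicted point map must equal the ground-truth point map exactly.
#'
#' The oracle identifies the region through the `region` attribute that
#' [predict_pointmap()] attaches to each crop before prediction.
#'
#' @param mask the photograph's [label_mask()].
#' @return a trained `tongue_classifier` handle.
#' @export
oracle_classifier <- function(mask) {
  fn <- function(patch) {
    region <- attr(patch, "region")
    if (is.null(region)) stop_validation("oracle needs a region-tagged patch")
    lab <- label_region(mask, region)
    p <- rep(0, 3); p[lab + 1L] <- 1
    p
  }
  train_classifier(list(), integer(0),
                   classifier_config("external", predict_fn = fn))
}

#' Save / load a classifier checkpoint
#'
#' Checkpoints are plain-text JSON holding the backbone, configuration and
#' model parameters. External-backend classifiers hold a closure and cannot
#' be serialised.
#'
#' @param handle a `tongue_classifier`.
#' @param path checkpoint file path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the restored `tongue_classifier`.
#' @export
save_classifier <- function(handle, path) {
  if (handle$backbone == "external") {
    stop_validation("external classifiers cannot be serialised")
  }
  cfg <- handle$config
  cfg$predict_fn <- NULL
  obj <- list(backbone = handle$backbone, config = unclass(cfg),
              model = serialise_model(handle$backbone, handle$model),
              report = handle$report)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(classifier_config, c(list(backbone = obj$backbone),
                 obj$config[c("learning_rate", "momentum", "dropout_rate",
                              "epochs", "batch_size", "seed", "input_size")]))
  model <- deserialise_model(obj$backbone, obj$model)
  structure(list(backbone = obj$backbone, model = model, config = cfg,
                 report = as.data.frame(obj$report)),
            class = "tongue_classifier")
}

serialise_model <- function(backbone, model) {
  if (backbone == "texture-baseline") {
    list(centroids = model$centroids, scale = model$scale)
  } else {
    lapply(model$weights, function(w) list(dim = dim(w) %||% length(w),
                                           data = as.numeric(w)))
  }
}

deserialise_model <- function(backbone, m) {
  if (backbone == "texture-baseline") {
    list(centroids = matrix(unlist(m$centroids), nrow = 3),
         scale = as.numeric(unlist(m$scale)), report = NULL)
  } else {
    weights <- lapply(m, function(w) {
      d <- as.integer(unlist(w$dim))
      v <- as.numeric(unlist(w$data))
      if (length(d) > 1L) array(v, dim = d) else v
    })
    list(weights = weights, report = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
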