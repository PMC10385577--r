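# A compact convolutional network trained from scratch with SGD + momentum.
# Implemented with im2col matrix products in plain R: small enough to train
# on one CPU in minutes, and bit-reproducible given the seed (no threads, no
# external learning runtime).
#
# Architecture (input 96 x 96 x 3, values scaled to [0, 1]):
#   fixed 4x4 average-pool stem -> 24 x 24 x 3
#   conv 3x3 -> 8,  ReLU, maxpool 2 -> 12 x 12 x 8
#   conv 3x3 -> 16, ReLU, maxpool 2 ->  6 x  6 x 16
#   conv 3x3 -> 32, ReLU, global average pool -> 32
#   dropout(rate) -> dense 32 -> 3 -> softmax, cross-entropy loss

cnn_dims <- list(c1 = c(in_ = 3L, out = 8L), c2 = c(in_ = 8L, out = 16L),
                 c3 = c(in_ = 16L, out = 32L), fc = c(in_ = 32L, out = 3L))

# 4x4 average pool of [n, 96, 96, 3] -> [n, 24, 24, 3], centred at zero
cnn_stem <- function(x) {
  n <- dim(x)[1]
  dim(x) <- c(n, 4L, 24L, 4L, 24L, 3L)
  s <- x[, 1, , , , , drop = FALSE] + x[, 2, , , , , drop = FALSE] +
       x[, 3, , , , , drop = FALSE] + x[, 4, , , , , drop = FALSE]
  dim(s) <- c(n, 24L, 4L, 24L, 3L)
  s2 <- s[, , 1, , , drop = FALSE] + s[, , 2, , , drop = FALSE] +
        s[, , 3, , , drop = FALSE] + s[, , 4, , , drop = FALSE]
  dim(s2) <- c(n, 24L, 24L, 3L)
  s2 / 16 - 0.5
}

# im2col for a same-padded 3x3 convolution on [n, h, w, c]:
# returns [(n*h*w) x (9c)] with offset-major column blocks.
cnn_im2col <- function(x) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; c <- d[4]
  pad <- array(0, dim = c(n, h + 2L, w + 2L, c))
  pad[, 2:(h + 1L), 2:(w + 1L), ] <- x
  out <- matrix(0, nrow = n * h * w, ncol = 9L * c)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    slice <- pad[, di + seq_len(h), dj + seq_len(w), , drop = FALSE]
    out[, k * c + seq_len(c)] <- matrix(slice, nrow = n * h * w)
    k <- k + 1L
  }
  out
}

# scatter-add of column gradients back onto the input, reversing cnn_im2col
cnn_col2im <- function(dcols, n, h, w, c) {
  gpad <- array(0, dim = c(n, h + 2L, w + 2L, c))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    blk <- array(dcols[, k * c + seq_len(c)], dim = c(n, h, w, c))
    gpad[, di + seq_len(h), dj + seq_len(w), ] <-
      gpad[, di + seq_len(h), dj + seq_len(w), , drop = FALSE] + blk
    k <- k + 1L
  }
  gpad[, 2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

cnn_conv_forward <- function(x, W, b) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]
  cols <- cnn_im2col(x)
  out <- sweep(cols %*% W, 2L, b, "+")
  list(out = array(out, dim = c(n, h, w, ncol(W))), cols = cols)
}

cnn_conv_backward <- function(dout, cache_cols, W, n, h, w, c_in) {
  dmat <- matrix(dout, nrow = n * h * w)
  dW <- crossprod(cache_cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(W)
  dx <- cnn_col2im(dcols, n, h, w, c_in)
  list(dx = dx, dW = dW, db = db)
}

cnn_maxpool <- function(x) {
  d <- dim(x); h <- d[2]; w <- d[3]
  i1 <- seq(1L, h, 2L); i2 <- seq(2L, h, 2L)
  j1 <- seq(1L, w, 2L); j2 <- seq(2L, w, 2L)
  s <- list(x[, i1, j1, , drop = FALSE], x[, i2, j1, , drop = FALSE],
            x[, i1, j2, , drop = FALSE], x[, i2, j2, , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # deterministic tie rule: the earliest slot in (1,2,3,4) order wins
  taken <- array(FALSE, dim = dim(m))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    mk <- (s[[k]] == m) & !taken
    taken <- taken | mk
    masks[[k]] <- mk
  }
  list(out = m, masks = masks, in_dim = d)
}

cnn_maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, dim = d)
  i1 <- seq(1L, d[2], 2L); i2 <- seq(2L, d[2], 2L)
  j1 <- seq(1L, d[3], 2L); j2 <- seq(2L, d[3], 2L)
  dx[, i1, j1, ] <- dout * cache$masks[[1]]
  dx[, i2, j1, ] <- dx[, i2, j1, , drop = FALSE] + dout * cache$masks[[2]]
  dx[, i1, j2, ] <- dx[, i1, j2, , drop = FALSE] + dout * cache$masks[[3]]
  dx[, i2, j2, ] <- dx[, i2, j2, , drop = FALSE] + dout * cache$masks[[4]]
  dx
}

cnn_gap <- function(x) {
  d <- dim(x); n <- d[1]; hw <- d[2] * d[3]; f <- d[4]
  m <- array(x, dim = c(n, hw, f))
  colSums(aperm(m, c(2L, 1L, 3L))) / hw
}

cnn_gap_backward <- function(dgap, h, w) {
  n <- nrow(dgap); f <- ncol(dgap); hw <- h * w
  m <- aperm(array(rep(dgap / hw, each = hw), dim = c(hw, n, f)), c(2L, 1L, 3L))
  array(m, dim = c(n, h, w, f))
}

cnn_init_weights <- function() {
  he <- function(fan_in, fan_out, k = 9L) {
    matrix(stats::rnorm(fan_in * k * fan_out, sd = sqrt(2 / (fan_in * k))),
           nrow = fan_in * k, ncol = fan_out)
  }
  list(W1 = he(3L, 8L), b1 = numeric(8L),
       W2 = he(8L, 16L), b2 = numeric(16L),
       W3 = he(16L, 32L), b3 = numeric(32L),
       W4 = matrix(stats::rnorm(32L * 3L, sd = sqrt(2 / 32)), 32L, 3L),
       b4 = numeric(3L))
}

cnn_forward <- function(x24, weights, dropout_mask = NULL) {
  n <- dim(x24)[1]
  c1 <- cnn_conv_forward(x24, weights$W1, weights$b1)
  r1 <- pmax(c1$out, 0)
  p1 <- cnn_maxpool(r1)
  c2 <- cnn_conv_forward(p1$out, weights$W2, weights$b2)
  r2 <- pmax(c2$out, 0)
  p2 <- cnn_maxpool(r2)
  c3 <- cnn_conv_forward(p2$out, weights$W3, weights$b3)
  r3 <- pmax(c3$out, 0)
  gap <- cnn_gap(r3)
  gd <- if (is.null(dropout_mask)) gap else gap * dropout_mask
  logits <- sweep(gd %*% weights$W4, 2L, weights$b4, "+")
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, logits = logits, gap = gap, gd = gd,
       c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
       c3 = c3, r3 = r3, n = n)
}

cnn_backward <- function(fw, weights, y_onehot, dropout_mask = NULL) {
  n <- fw$n
  dlogits <- (fw$probs - y_onehot) / n
  dW4 <- crossprod(fw$gd, dlogits)
  db4 <- colSums(dlogits)
  dgd <- dlogits %*% t(weights$W4)
  dgap <- if (is.null(dropout_mask)) dgd else dgd * dropout_mask
  dr3 <- cnn_gap_backward(dgap, 6L, 6L)
  dc3 <- dr3 * (fw$r3 > 0)
  b3g <- cnn_conv_backward(dc3, fw$c3$cols, weights$W3, n, 6L, 6L, 16L)
  dp2 <- cnn_maxpool_backward(b3g$dx, fw$p2)
  dc2 <- dp2 * (fw$r2 > 0)
  b2g <- cnn_conv_backward(dc2, fw$c2$cols, weights$W2, n, 12L, 12L, 8L)
  dp1 <- cnn_maxpool_backward(b2g$dx, fw$p1)
  dc1 <- dp1 * (fw$r1 > 0)
  b1g <- cnn_conv_backward(dc1, fw$c1$cols, weights$W1, n, 24L, 24L, 3L)
  list(W1 = b1g$dW, b1 = b1g$db, W2 = b2g$dW, b2 = b2g$db,
       W3 = b3g$dW, b3 = b3g$db, W4 = dW4, b4 = db4)
}

cnn_prepare <- function(patches, size = 96L) {
  n <- length(patches)
  x <- array(0, dim = c(n, size, size, 3L))
  for (i in seq_len(n)) {
    p <- patches[[i]]
    if (img_width(p) != size || img_height(p) != size) p <- resize_patch(p, size)
    x[i, , , ] <- unclass(p) / 255
  }
  cnn_stem(x)
}

#' Train the small CNN backend
#'
#' Runs minibatch stochastic gradient descent with momentum on the compact
#' convolutional network described in the package vignette. All randomness
#' (weight initialisation, epoch shuffling, dropout masks) flows from
#' `config$seed`, so training is bit-reproducible.
#'
#' Normally called through [train_classifier()] with a
#' `backbone = "small-cnn"` configuration.
#'
#' @inheritParams train_classifier
#' @return list with `weights` and a per-epoch `report` data frame.
#' @export
train_small_cnn <- function(patches, labels, config,
                            valid_patches = NULL, valid_labels = NULL) {
  x <- cnn_prepare(patches, config$input_size)
  n <- dim(x)[1]
  y <- as.integer(labels)
  xv <- if (!is.null(valid_patches)) cnn_prepare(valid_patches, config$input_size)
  keep <- 1 - config$dropout_rate
  with_seed(config$seed, {
    weights <- cnn_init_weights()
    vel <- lapply(weights, function(w) w * 0)
    report <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      tot_loss <- 0; tot_correct <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        xb <- x[idx, , , , drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        mask <- if (keep < 1) {
          matrix((stats::runif(nb * 32L) < keep) / keep, nb, 32L)
        }
        fw <- cnn_forward(xb, weights, mask)
        onehot <- matrix(0, nb, 3L)
        onehot[cbind(seq_len(nb), yb + 1L)] <- 1
        pt <- fw$probs[cbind(seq_len(nb), yb + 1L)]
        tot_loss <- tot_loss - sum(log(pmax(pt, 1e-12)))
        tot_correct <- tot_correct +
          sum(max.col(fw$probs, ties.method = "first") - 1L == yb)
        grads <- cnn_backward(fw, weights, onehot, mask)
        for (nm in names(weights)) {
          vel[[nm]] <- config$momentum * vel[[nm]] -
            config$learning_rate * grads[[nm]]
          weights[[nm]] <- weights[[nm]] + vel[[nm]]
        }
      }
      vrow <- c(NA_real_, NA_real_)
      if (!is.null(xv)) {
        fwv <- cnn_forward(xv, weights)
        ptv <- fwv$probs[cbind(seq_along(valid_labels), valid_labels + 1L)]
        vrow <- c(-mean(log(pmax(ptv, 1e-12))),
                  mean(max.col(fwv$probs, ties.method = "first") - 1L ==
                         valid_labels))
      }
      report[[epoch]] <- data.frame(epoch = epoch,
                                    train_loss = tot_loss / n,
                                    train_acc = tot_correct / n,
                                    valid_loss = vrow[1], valid_acc = vrow[2])
    }
    list(weights = weights, report = do.call(rbind, report))
  })
}

cnn_predict_probs <- function(model, patches) {
  x <- cnn_prepare(patches)
  fw <- cnn_forward(x, model$weights)
  fw$probs
}
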