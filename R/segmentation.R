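# Foreground segmentation of nuclei: a deterministic classical reference
# segmenter, the border-separation weight map, the weight-map-adapted focal
# loss, and a tiny trainable pixel-classifier backend. Any mask source
# (reference segmenter, trained backend, or masks imported from an external
# model) is accepted downstream.

#' Loss and weight-map configuration
#'
#' @param gamma Focusing exponent of the focal loss (>= 0). With
#'   `gamma = 0` and `alpha = 0.5` the loss reduces to half the mean binary
#'   cross-entropy.
#' @param alpha Class-balance weight of the positive class, in (0, 1).
#' @param w0 Amplitude of the border-separation term of the weight map.
#' @param sigma_px Length scale (pixels) of the border-separation term.
#' @param class_weights Named base weights for `background` and `foreground`
#'   pixels.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(gamma = 2, alpha = 0.25, w0 = 10, sigma_px = 5,
                        class_weights = c(background = 1, foreground = 1)) {
  stopifnot(gamma >= 0, alpha > 0, alpha < 1, w0 >= 0, sigma_px > 0,
            all(class_weights > 0))
  structure(list(gamma = gamma, alpha = alpha, w0 = w0, sigma_px = sigma_px,
                 class_weights = class_weights),
            class = "loss_config")
}

# Grayscale transform used by the reference segmenter: mean of the RGB
# channels, optionally inverted so that nuclei are always the dark phase.
roi_grayscale <- function(image, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  if (polarity == "bright") g <- 1 - g
  g
}

#' Deterministic reference segmentation of nuclei
#'
#' Classical pipeline: grayscale transform, Gaussian smoothing, a single
#' global threshold chosen by between-class variance maximization (Otsu), and
#' hole filling. Dark-stained blobs become foreground. Deterministic and
#' dependency-light; intended as the desk-scale mask source standing in for a
#' trained segmentation network.
#'
#' @param image Height x width x 3 array in \[0, 1\].
#' @param resolution_um_per_px Scan resolution, attached to the output mask.
#' @param sigma_px Gaussian smoothing SD in pixels (0 disables smoothing).
#' @param fill_holes Fill enclosed background holes inside foreground blobs.
#' @param polarity `"dark"` if nuclei are darker than background, `"bright"`
#'   for inverted-contrast input.
#' @return Binary 0/1 integer matrix with a `resolution_um_per_px`
#'   attribute. A blank (constant) image yields an all-zero mask.
#' @export
reference_segment <- function(image, resolution_um_per_px = 0.25,
                              sigma_px = 1, fill_holes = TRUE,
                              polarity = c("dark", "bright")) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  g <- roi_grayscale(image, polarity)
  if (sigma_px > 0)
    g <- as.matrix(EBImage::gblur(EBImage::Image(g), sigma = sigma_px))
  out <- matrix(0L, nrow(g), ncol(g))
  if (stats::sd(g) > 1e-8) {
    th <- EBImage::otsu(EBImage::Image(pmin(1, pmax(0, g))))
    out[g < th] <- 1L
    if (fill_holes)
      out <- matrix(as.integer(
        as.matrix(EBImage::fillHull(EBImage::Image(out))) > 0),
        nrow(out), ncol(out))
  }
  attr(out, "resolution_um_per_px") <- resolution_um_per_px
  out
}

#' Border-separation weight map
#'
#' Per-pixel weights `w = w_c + w0 * exp(-(d1 + d2)^2 / (2 sigma^2))` where
#' `d1` and `d2` are the Euclidean distances to the nearest and second-nearest
#' nucleus instance and `w_c` is the class base weight. Weights are maximal in
#' the thin background gaps between adjacent instances, which pushes a
#' segmenter trained under the weighted loss to keep touching nuclei
#' separated. With fewer than two instances `d2` is infinite and the border
#' term vanishes everywhere.
#'
#' @param gt_mask Integer instance label mask (0 = background).
#' @param cfg A [loss_config()] supplying `w0`, `sigma_px`, `class_weights`.
#' @return Numeric matrix of positive weights, same shape as `gt_mask`.
#' @export
compute_weight_map <- function(gt_mask, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"), is.matrix(gt_mask))
  labs <- sort(unique(gt_mask[gt_mask > 0]))
  wc <- ifelse(gt_mask > 0, cfg$class_weights[["foreground"]],
               cfg$class_weights[["background"]])
  if (length(labs) < 2L) return(wc + 0)  # border term zero
  d1 <- matrix(Inf, nrow(gt_mask), ncol(gt_mask))
  d2 <- d1
  for (k in labs) {
    dk <- as.matrix(EBImage::distmap(EBImage::Image(
      matrix(as.numeric(gt_mask != k), nrow(gt_mask)))))
    closer <- dk < d1
    d2 <- ifelse(closer, d1, pmin(d2, dk))
    d1 <- ifelse(closer, dk, d1)
  }
  wc + cfg$w0 * exp(-(d1 + d2)^2 / (2 * cfg$sigma_px^2))
}

#' Weight-map-adapted focal loss
#'
#' Mean over pixels of `w * alpha_t * (1 - p_t)^gamma * (-log p_t)`, where
#' `p_t` is the predicted probability of the true class and `alpha_t` is
#' `alpha` for foreground and `1 - alpha` for background pixels.
#' Probabilities are clamped to `[eps, 1 - eps]`; clamping at a mispredicted
#' pixel is reported with a message.
#'
#' @param prob_map Predicted foreground probabilities, matrix in (0, 1).
#' @param target Binary 0/1 ground-truth mask, same shape.
#' @param weights Per-pixel weight map (scalar or matrix), default 1.
#' @param cfg A [loss_config()].
#' @param eps Clamping epsilon.
#' @return Non-negative scalar; 0 iff every pixel is predicted perfectly.
#' @export
weighted_focal_loss <- function(prob_map, target, weights = 1,
                                cfg = loss_config(), eps = 1e-7) {
  stopifnot(all(dim(prob_map) == dim(target)))
  p <- prob_map
  wrong_extreme <- (p >= 1 & target == 0) | (p <= 0 & target == 1)
  if (any(wrong_extreme))
    message(sum(wrong_extreme),
            " pixel(s) at probability 0/1 with the wrong label; clamped")
  p <- pmin(1 - eps, pmax(eps, p))
  pt <- ifelse(target == 1, p, 1 - p)
  at <- ifelse(target == 1, cfg$alpha, 1 - cfg$alpha)
  mean(weights * at * (1 - pt)^cfg$gamma * (-log(pt)))
}

# Pixel features for the tiny backend: RGB, 5x5 local channel means, and
# grayscale intensity.
tiny_features <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  box <- matrix(1 / 25, 5, 5)
  f <- vector("list", 7)
  for (ch in 1:3) {
    f[[ch]] <- as.vector(image[, , ch])
    f[[ch + 3]] <- as.vector(as.matrix(
      EBImage::filter2(EBImage::Image(image[, , ch]), box)))
  }
  f[[7]] <- as.vector((image[, , 1] + image[, , 2] + image[, , 3]) / 3)
  do.call(cbind, f)
}

# Analytic gradient of the weighted focal loss of a logistic pixel model.
focal_grad <- function(X, y, w, beta, cfg, eps = 1e-7) {
  z <- drop(X %*% beta)
  p <- 1 / (1 + exp(-z))
  p <- pmin(1 - eps, pmax(eps, p))
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, cfg$alpha, 1 - cfg$alpha)
  s <- p * (1 - p) * ifelse(y == 1, 1, -1)          # d pt / d z
  dL_dpt <- at * (cfg$gamma * (1 - pt)^(pmax(cfg$gamma - 1, 0)) * log(pt) -
                  (1 - pt)^cfg$gamma / pt)
  g <- w * dL_dpt * s
  drop(crossprod(X, g)) / length(y)
}

#' Train the tiny segmentation backend
#'
#' A logistic pixel classifier over RGB, local-mean and intensity features,
#' trained by full-batch gradient descent on the weight-map-adapted focal
#' loss. One epoch is one gradient step over a fixed subsample of training
#' pixels; the returned model is the epoch with the lowest validation loss.
#' Deterministic given `seed`. This backend deliberately trades capacity for
#' desk-scale speed; it is one of several accepted mask sources, not a
#' reproduction of a deep segmentation network.
#'
#' @param fixtures List of training fixtures, each a list with `image` and
#'   instance label `mask` (as produced by [generate_nucleus_image()]).
#' @param val_fixtures Optional held-out fixtures for epoch selection; if
#'   omitted, the final epoch is used (with a warning).
#' @param cfg A [loss_config()].
#' @param epochs Number of gradient steps (>= 1).
#' @param lr Learning rate.
#' @param max_pixels Training-pixel subsample size per run.
#' @param seed Seed for the pixel subsample.
#' @return Object of class `tiny_segmenter` with `coefficients`, feature
#'   standardization stats, `history` (training/validation loss per epoch)
#'   and `best_epoch`.
#' @export
train_tiny_segmenter <- function(fixtures, val_fixtures = NULL,
                                 cfg = loss_config(), epochs = 40L,
                                 lr = 1, max_pixels = 50000L, seed = 1L) {
  stopifnot(length(fixtures) >= 1)
  if (epochs < 1L) stop("epochs must be >= 1; an untrained model is not usable")
  gather <- function(fxs) {
    Xs <- list(); ys <- list(); ws <- list()
    for (f in fxs) {
      Xs[[length(Xs) + 1L]] <- tiny_features(f$image)
      ys[[length(ys) + 1L]] <- as.numeric(as.vector(f$mask) > 0)
      ws[[length(ws) + 1L]] <- as.vector(compute_weight_map(f$mask, cfg))
    }
    list(X = do.call(rbind, Xs), y = unlist(ys), w = unlist(ws))
  }
  tr <- gather(fixtures)
  with_seed(seed, {
    idx <- if (nrow(tr$X) > max_pixels)
      sample.int(nrow(tr$X), max_pixels) else seq_len(nrow(tr$X))
    X <- tr$X[idx, , drop = FALSE]; y <- tr$y[idx]; w <- tr$w[idx]
    ctr <- colMeans(X); scl <- pmax(apply(X, 2, stats::sd), 1e-8)
    Xs <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
    has_val <- !is.null(val_fixtures) && length(val_fixtures) > 0
    if (has_val) {
      va <- gather(val_fixtures)
      vidx <- if (nrow(va$X) > max_pixels)
        sample.int(nrow(va$X), max_pixels) else seq_len(nrow(va$X))
      Xv <- cbind(1, sweep(sweep(va$X[vidx, , drop = FALSE], 2, ctr),
                           2, scl, "/"))
      yv <- va$y[vidx]; wv <- va$w[vidx]
    } else {
      warning("no validation fixtures; using the last epoch")
    }
    beta <- numeric(ncol(Xs))
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(epoch = NA_integer_, loss = Inf, beta = beta)
    loss_of <- function(Xm, yy, ww) {
      p <- 1 / (1 + exp(-drop(Xm %*% beta)))
      weighted_focal_loss(matrix(p, 1), matrix(yy, 1),
                          matrix(ww, 1), cfg)
    }
    for (e in seq_len(epochs)) {
      beta <- beta - lr * focal_grad(Xs, y, w, beta, cfg)
      tl <- loss_of(Xs, y, w)
      vl <- if (has_val) loss_of(Xv, yv, wv) else NA_real_
      history[e, ] <- list(e, tl, vl)
      sel <- if (has_val) vl else tl
      if (has_val && sel < best$loss)
        best <- list(epoch = e, loss = sel, beta = beta)
    }
    if (!has_val) best <- list(epoch = epochs, loss = NA_real_, beta = beta)
    structure(list(coefficients = best$beta, center = ctr, scale = scl,
                   cfg = cfg, history = history, best_epoch = best$epoch),
              class = "tiny_segmenter")
  })
}

#' Predict foreground probabilities with the tiny backend
#'
#' @param object A `tiny_segmenter`.
#' @param image Height x width x 3 array in \[0, 1\].
#' @param ... Unused.
#' @return Matrix of foreground probabilities in (0, 1).
#' @export
predict.tiny_segmenter <- function(object, image, ...) {
  X <- tiny_features(image)
  Xs <- cbind(1, sweep(sweep(X, 2, object$center), 2, object$scale, "/"))
  p <- 1 / (1 + exp(-drop(Xs %*% object$coefficients)))
  matrix(p, dim(image)[1], dim(image)[2])
}

#' Binary mask from the tiny backend
#'
#' @param object A `tiny_segmenter`.
#' @param image RGB array.
#' @param resolution_um_per_px Resolution attached to the mask.
#' @param threshold Probability cutoff.
#' @return Binary 0/1 mask with resolution attribute.
#' @export
segment_with <- function(object, image, resolution_um_per_px = 0.25,
                         threshold = 0.5) {
  p <- predict(object, image)
  out <- matrix(as.integer(p >= threshold), nrow(p), ncol(p))
  attr(out, "resolution_um_per_px") <- resolution_um_per_px
  out
}
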