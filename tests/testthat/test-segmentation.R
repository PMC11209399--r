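test_that("reference segmenter recovers dense nuclei and handles blanks", {
  blank <- array(0.8, c(40, 50, 3))
  m <- reference_segment(blank)
  expect_equal(sum(m), 0)

  roi <- small_roi(seed = 7, n = 50)
  pred <- reference_segment(roi$image, 0.25)
  expect_gte(dice(pred, roi$mask), 0.85)
})

test_that("polarity flag makes inverted-contrast input equivalent", {
  roi <- small_roi(seed = 9, n = 25, w = 420, h = 320)
  inv <- 1 - roi$image
  m1 <- reference_segment(roi$image, polarity = "dark")
  m2 <- reference_segment(inv, polarity = "bright")
  expect_identical(unclass(m1), unclass(m2))
})

test_that("reference segmentation is idempotent on its own output", {
  roi <- small_roi(seed = 12, n = 25, w = 420, h = 320)
  m1 <- reference_segment(roi$image)
  two_tone <- array(ifelse(m1 == 1, 0.2, 0.9), c(nrow(m1), ncol(m1), 3))
  m2 <- reference_segment(two_tone, sigma_px = 0)
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])
})

test_that("weight map matches the brute-force distance formula", {
  m <- matrix(0L, 12, 12)
  m[3:4, 3:4] <- 1L; m[8:9, 8:9] <- 2L; m[2:3, 9:10] <- 3L
  cfg <- loss_config(w0 = 10, sigma_px = 5)
  expect_equal(compute_weight_map(m, cfg), brute_weight_map(m, cfg),
               tolerance = 1e-6)
})

test_that("weight map border term follows the Gaussian closed form", {
  # two single-pixel instances d apart: between-gap pixels see d1 + d2 = d
  cfg <- loss_config(w0 = 10, sigma_px = 2)
  gap <- cfg$sigma_px * sqrt(2 * log(2))  # border term = w0 / 2
  d <- round(gap)
  m <- matrix(0L, 7, 20)
  m[4, 5] <- 1L; m[4, 5 + d] <- 2L
  w <- compute_weight_map(m, cfg)
  mid <- w[4, 5 + 1]  # on the segment: d1 + d2 = d exactly
  expect_equal(mid, 1 + cfg$w0 * exp(-d^2 / (2 * cfg$sigma_px^2)),
               tolerance = 1e-6)
  # at the instances themselves d1 = 0, d2 = d: same sum, maximal weight band
  expect_equal(w[4, 5], mid, tolerance = 1e-6)
})

test_that("weight map degenerates to class weights without a second instance", {
  cfg <- loss_config(w0 = 10, sigma_px = 3,
                     class_weights = c(background = 1, foreground = 2.5))
  single <- matrix(0L, 10, 10); single[4:6, 4:6] <- 1L
  w <- compute_weight_map(single, cfg)
  expect_equal(unique(as.vector(w)), c(1, 2.5))

  none <- matrix(0L, 5, 5)
  expect_equal(as.vector(compute_weight_map(none, cfg)), rep(1, 25))
})

test_that("far-apart instances contribute a border term below 1e-3 w0", {
  cfg <- loss_config(w0 = 10, sigma_px = 2)
  m <- matrix(0L, 10, 40); m[5, 3] <- 1L; m[5, 38] <- 2L  # 35 px > 6 sigma
  w <- compute_weight_map(m, cfg)
  inner <- w[, 10:30]
  expect_lt(max(inner - 1), 1e-3 * cfg$w0)
})

test_that("weighted focal loss reproduces hand-computed values", {
  cfg <- loss_config(gamma = 2, alpha = 0.25)
  expect_equal(
    weighted_focal_loss(matrix(0.5), matrix(1), matrix(2), cfg),
    2 * 0.25 * 0.5^2 * (-log(0.5)), tolerance = 1e-12)

  # gamma = 0, alpha = 0.5, unit weights: half the mean binary cross-entropy
  set.seed(1)
  p <- matrix(runif(100, 0.05, 0.95), 10)
  y <- matrix(rbinom(100, 1, 0.5), 10)
  bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(
    weighted_focal_loss(p, y, 1, loss_config(gamma = 0, alpha = 0.5)),
    0.5 * bce, tolerance = 1e-12)

  # perfect prediction: loss tends to zero
  expect_lt(weighted_focal_loss(matrix(1 - 1e-9, 3, 3), matrix(1, 3, 3),
                                1, cfg), 1e-15)
})

test_that("focal loss clamps and reports confident wrong predictions", {
  expect_message(
    l <- weighted_focal_loss(matrix(1), matrix(0), 1, loss_config()),
    "clamped")
  expect_true(is.finite(l) && l > 0)
})

test_that("raising the true-class probability never increases the loss", {
  cfg <- loss_config()
  set.seed(3)
  for (rep in 1:20) {
    y <- matrix(rbinom(16, 1, 0.5), 4)
    p <- matrix(runif(16, 0.1, 0.85), 4)
    i <- sample(16, 1)
    l0 <- weighted_focal_loss(p, y, 1, cfg)
    p[i] <- p[i] + if (y[i] == 1) 0.1 else -0.1
    expect_lte(weighted_focal_loss(p, y, 1, cfg), l0)
  }
})

test_that("tiny segmenter trains to usable masks and selects by val loss", {
  train <- lapply(1:4, function(s) small_roi(seed = s, n = 15, w = 320,
                                             h = 240))
  held <- lapply(8:9, function(s) small_roi(seed = s, n = 15, w = 320,
                                            h = 240))
  model <- train_tiny_segmenter(train, val_fixtures = held[1],
                                epochs = 30, seed = 1)
  expect_s3_class(model, "tiny_segmenter")
  expect_true(model$best_epoch >= 1 && model$best_epoch <= 30)
  d <- dice(segment_with(model, held[[2]]$image), held[[2]]$mask)
  expect_gte(d, 0.75)
})

test_that("tiny segmenter training is deterministic and rejects epochs = 0", {
  train <- list(small_roi(seed = 2, n = 8, w = 230, h = 180))
  m1 <- suppressWarnings(train_tiny_segmenter(train, epochs = 5, seed = 4))
  m2 <- suppressWarnings(train_tiny_segmenter(train, epochs = 5, seed = 4))
  expect_identical(m1$history, m2$history)
  expect_warning(train_tiny_segmenter(train, epochs = 5, seed = 4),
                 "last epoch")
  expect_error(train_tiny_segmenter(train, epochs = 0), "epochs")
})
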