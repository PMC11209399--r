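# Independent oracles and fixture builders used across the suite. Each
# oracle is a deliberately naive re-derivation (brute force, enumeration,
# closed form) kept independent of the package's implementation path.

# Brute-force AUC: pairwise comparison probability with ties counting 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force connected-component labeling by breadth-first flood fill.
brute_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  k <- 0L
  for (idx in which(mask > 0)) {
    r0 <- (idx - 1) %% H + 1; c0 <- (idx - 1) %/% H + 1
    if (lab[r0, c0] > 0) next
    k <- k + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[i]; c <- p[2] + nb$dc[i]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] > 0 && lab[r, c] == 0) {
          lab[r, c] <- k
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Maximum one-to-one matching size by exhaustive enumeration over subsets of
# candidate pairs (pairs: data frame with pred, gt columns). Feasible for a
# handful of pairs only.
brute_max_matching <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0) return(0L)
  best <- 0L
  for (s in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(s, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    if (anyDuplicated(pairs$pred[sel]) || anyDuplicated(pairs$gt[sel])) next
    best <- length(sel)
  }
  best
}

# Explicit Cox partial log-likelihood for untied event times; maximized on a
# grid + optimize() as a one-dimensional oracle.
brute_cox_hr <- function(x, time, status) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; status <- status[ord]
  stopifnot(!anyDuplicated(time[status == 1]))
  pll <- function(b) {
    sum(vapply(which(status == 1), function(i) {
      risk <- time >= time[i]
      x[i] * b - log(sum(exp(x[risk] * b)))
    }, numeric(1)))
  }
  exp(stats::optimize(pll, c(-10, 10), maximum = TRUE)$maximum)
}

# Rasterized disk / ellipse pixel sets (row, col), axes in pixels.
ellipse_pixels <- function(a, b, angle = 0, center = c(a + 2, a + 2)) {
  r <- seq_len(ceiling(2 * a + 4)); c <- r
  g <- expand.grid(row = r, col = c)
  dx <- g$col - center[2]; dy <- g$row - center[1]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[inside, c("row", "col")])
}

# Small seeded ROI fixture shared by several tests.
small_roi <- function(seed = 7, n = 50, w = 500, h = 375, overlap = 0,
                      irregularity = 0.1) {
  generate_nucleus_image(image_spec(
    width_px = w, height_px = h, n_nuclei = n,
    overlap_fraction = overlap, irregularity = irregularity, seed = seed))
}

# Brute-force weight map: direct pairwise pixel distances to each instance.
brute_weight_map <- function(gt_mask, cfg) {
  labs <- sort(unique(gt_mask[gt_mask > 0]))
  H <- nrow(gt_mask); W <- ncol(gt_mask)
  wc <- ifelse(gt_mask > 0, cfg$class_weights[["foreground"]],
               cfg$class_weights[["background"]])
  if (length(labs) < 2) return(wc + 0)
  coords <- expand.grid(row = seq_len(H), col = seq_len(W))
  dists <- sapply(labs, function(k) {
    pk <- which(gt_mask == k)
    pr <- (pk - 1) %% H + 1; pc <- (pk - 1) %/% H + 1
    apply(coords, 1, function(p)
      sqrt(min((p[1] - pr)^2 + (p[2] - pc)^2)))
  })
  d_sorted <- t(apply(dists, 1, sort))
  wc + cfg$w0 * matrix(exp(-(d_sorted[, 1] + d_sorted[, 2])^2 /
                             (2 * cfg$sigma_px^2)), H, W)
}
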