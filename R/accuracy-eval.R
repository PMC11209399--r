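# Segmentation quality against ground truth: pixel-level Dice, object-level
# precision/recall/F1 via explicit one-to-one matching, and per-parameter
# RMSE with the RMSE-to-range ratio.

#' Dice coefficient of two binary masks
#'
#' `2 |P & G| / (|P| + |G|)`; defined as 1 when both masks are empty.
#'
#' @param pred,gt Binary 0/1 matrices of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(pred, gt) {
  stopifnot(all(dim(pred) == dim(gt)))
  p <- sum(pred > 0); g <- sum(gt > 0)
  if (p + g == 0) return(1)
  2 * sum(pred > 0 & gt > 0) / (p + g)
}

# pairwise overlap table between two label masks: data frame
# (pred, gt, inter, iou) for every intersecting pair
overlap_pairs <- function(pred, gt) {
  both <- pred > 0 & gt > 0
  if (!any(both))
    return(data.frame(pred = integer(0), gt = integer(0),
                      inter = integer(0), iou = numeric(0)))
  tab <- table(pred = pred[both], gt = gt[both])
  idx <- which(tab > 0, arr.ind = TRUE)
  pl <- as.integer(rownames(tab))[idx[, 1]]
  gl <- as.integer(colnames(tab))[idx[, 2]]
  inter <- tab[idx]
  psz <- tabulate(pred[pred > 0])
  gsz <- tabulate(gt[gt > 0])
  data.frame(pred = pl, gt = gl, inter = as.integer(inter),
             iou = inter / (psz[pl] + gsz[gl] - inter))
}

#' Object-level matching of predicted and ground-truth instances
#'
#' Greedy one-to-one matching by descending overlap: candidate pairs must
#' satisfy the matching criterion (default IoU >= `iou_cutoff`; alternative
#' `"centroid"`: the ground-truth centroid falls inside the predicted
#' object), and each predicted/true object is used at most once. Precision =
#' matches / n_pred, recall = matches / n_gt, F1 = 2PR / (P + R). When both
#' masks are empty all metrics are 1 by convention.
#'
#' @param pred,gt Integer instance label masks of identical shape.
#' @param criterion `"iou"` or `"centroid"`.
#' @param iou_cutoff Minimum IoU for a valid match (criterion `"iou"`).
#' @return Object of class `segmentation_quality`: list with `f1`,
#'   `precision`, `recall`, `n_matches`, `n_pred`, `n_gt` and the `matches`
#'   table.
#' @export
match_objects <- function(pred, gt, criterion = c("iou", "centroid"),
                          iou_cutoff = 0.5) {
  stopifnot(all(dim(pred) == dim(gt)))
  criterion <- match.arg(criterion)
  n_pred <- length(unique(pred[pred > 0]))
  n_gt <- length(unique(gt[gt > 0]))
  if (n_pred == 0 && n_gt == 0) {
    message("both masks empty; metrics defined as 1")
    return(structure(list(f1 = 1, precision = 1, recall = 1, n_matches = 0L,
                          n_pred = 0L, n_gt = 0L,
                          matches = data.frame()),
                     class = "segmentation_quality"))
  }
  pairs <- overlap_pairs(pred, gt)
  if (criterion == "iou") {
    pairs <- pairs[pairs$iou >= iou_cutoff, , drop = FALSE]
  } else {
    ok <- vapply(seq_len(nrow(pairs)), function(i) {
      px <- which(gt == pairs$gt[i])
      r <- round(mean((px - 1) %% nrow(gt)) + 1)
      c <- round(mean((px - 1) %/% nrow(gt)) + 1)
      pred[r, c] == pairs$pred[i]
    }, logical(1))
    pairs <- pairs[ok, , drop = FALSE]
  }
  # greedy descending IoU, deterministic tie-break on (pred, gt) labels
  pairs <- pairs[order(-pairs$iou, pairs$pred, pairs$gt), , drop = FALSE]
  used_p <- used_g <- integer(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$pred[i] %in% used_p) && !(pairs$gt[i] %in% used_g)) {
      keep[i] <- TRUE
      used_p <- c(used_p, pairs$pred[i])
      used_g <- c(used_g, pairs$gt[i])
    }
  }
  m <- sum(keep)
  precision <- if (n_pred > 0) m / n_pred else NA_real_
  recall <- if (n_gt > 0) m / n_gt else NA_real_
  f1 <- if (isTRUE(precision + recall > 0))
    2 * precision * recall / (precision + recall) else 0
  structure(list(f1 = f1, precision = precision, recall = recall,
                 n_matches = as.integer(m), n_pred = as.integer(n_pred),
                 n_gt = as.integer(n_gt),
                 matches = pairs[keep, , drop = FALSE]),
            class = "segmentation_quality")
}

#' @export
print.segmentation_quality <- function(x, ...) {
  cat(sprintf(
    "<segmentation_quality> F1 %.4f  precision %.4f  recall %.4f  (%d/%d pred, %d gt)\n",
    x$f1, x$precision, x$recall, x$n_matches, x$n_pred, x$n_gt))
  invisible(x)
}

#' Root mean squared error
#'
#' @param predicted,truth Paired numeric vectors.
#' @return `sqrt(mean((predicted - truth)^2))`.
#' @export
rmse <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) >= 1)
  sqrt(mean((predicted - truth)^2))
}

#' RMSE-to-range ratio
#'
#' RMSE divided by the range (max - min) of the ground-truth values across
#' the evaluated cases, describing the size of the error relative to the
#' spread of the data.
#'
#' @param predicted,truth Paired numeric vectors; `truth` must have a
#'   positive range.
#' @return Ratio (unitless; multiply by 100 for percent).
#' @export
rmse_to_range <- function(predicted, truth) {
  rg <- diff(range(truth))
  if (rg <= 0) stop("ground-truth range is zero; ratio undefined")
  rmse(predicted, truth) / rg
}
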