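# The manual-morphometry sampling procedure: 5 x 6 grid partition, meandering
# traversal from the upper-left corner, accumulation of whole grid cells until
# at least 100 nuclei are annotated, and exclusion of margin-cut nuclei.

#' Grid plan for manual subsampling
#'
#' Partitions the ROI into `rows x cols` (default 5 x 6 = 30) equally sized
#' cells that tile the image exactly, and fixes the meandering traversal
#' order: left-to-right on the first row, right-to-left on the second, and so
#' on, starting from the upper-left corner.
#'
#' @param width_px,height_px ROI size in pixels.
#' @param rows,cols Grid dimensions.
#' @return Object of class `grid_plan` with the cell table (`cells`, in
#'   meander order with 1-based inclusive pixel ranges) and the break
#'   vectors.
#' @export
grid_plan <- function(width_px, height_px, rows = 5L, cols = 6L) {
  stopifnot(width_px >= cols, height_px >= rows)
  xb <- round(seq(0, width_px, length.out = cols + 1))
  yb <- round(seq(0, height_px, length.out = rows + 1))
  cells <- do.call(rbind, lapply(seq_len(rows), function(i) {
    js <- if (i %% 2 == 1) seq_len(cols) else rev(seq_len(cols))
    data.frame(grid_row = i, grid_col = js,
               col_min = xb[js] + 1, col_max = xb[js + 1],
               row_min = yb[i] + 1, row_max = yb[i + 1])
  }))
  cells$order <- seq_len(nrow(cells))
  structure(list(rows = rows, cols = cols,
                 width_px = width_px, height_px = height_px,
                 x_breaks = xb, y_breaks = yb, cells = cells),
            class = "grid_plan")
}

# meander position of the cell containing 1-based pixel (row, col)
cell_order_of <- function(plan, row, col) {
  gi <- findInterval(row - 1, plan$y_breaks, rightmost.closed = TRUE)
  gj <- findInterval(col - 1, plan$x_breaks, rightmost.closed = TRUE)
  gi <- pmin(pmax(gi, 1L), plan$rows)
  gj <- pmin(pmax(gj, 1L), plan$cols)
  jj <- ifelse(gi %% 2 == 1, gj, plan$cols + 1L - gj)
  (gi - 1L) * plan$cols + jj
}

#' Assign annotations to grid cells
#'
#' Each annotation polygon is assigned to exactly one cell: the earliest cell
#' in meander order containing any of its pixels (an annotation straddling a
#' grid line therefore counts once, in the cell reached first). Annotations
#' cut at the image margin — any pixel on the image border, or geometry
#' extending outside the canvas — are excluded.
#'
#' @param polygons List of `list(label, vertices)` annotations (0-based
#'   (x, y) vertex coordinates).
#' @param plan A [grid_plan()].
#' @return Data frame with `label`, `cell_order` (meander position, NA if
#'   excluded), `n_pixels` and `excluded`.
#' @export
assign_to_grid <- function(polygons, plan) {
  stopifnot(inherits(plan, "grid_plan"))
  W <- plan$width_px; H <- plan$height_px
  res <- lapply(polygons, function(p) {
    v <- p$vertices
    outside <- any(v[, 1] < 0 | v[, 1] > W - 1 | v[, 2] < 0 | v[, 2] > H - 1)
    px <- rasterize_polygon_pixels(v, W, H)
    on_border <- nrow(px) > 0 &&
      any(px[, 1] == 1 | px[, 1] == H | px[, 2] == 1 | px[, 2] == W)
    excluded <- outside || on_border || nrow(px) == 0
    cell <- if (excluded) NA_integer_ else
      min(cell_order_of(plan, px[, 1], px[, 2]))
    data.frame(label = p$label, cell_order = cell,
               n_pixels = nrow(px), excluded = excluded)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Grid-wise subsample of annotations
#'
#' Traverses the grid cells in meander order, accumulating all annotations of
#' each cell, and stops at the first cell boundary at which at least `min_n`
#' annotations have been accumulated (i.e., the cell in progress when the
#' count is reached is still completed). Excluded (margin-cut) annotations do
#' not count. If fewer than `min_n` annotations exist in total, all are
#' returned with a warning.
#'
#' @param assignments Output of [assign_to_grid()].
#' @param plan The [grid_plan()] used.
#' @param min_n Minimum number of annotations (default 100).
#' @return List with `labels` (selected annotation labels), `n_selected`,
#'   `cells_used` (number of cells traversed), and `log` (per-cell counts and
#'   cumulative totals in meander order).
#' @export
grid_subsample <- function(assignments, plan, min_n = 100L) {
  ok <- assignments[!assignments$excluded, , drop = FALSE]
  n_cells <- plan$rows * plan$cols
  counts <- tabulate(ok$cell_order, nbins = n_cells)
  cum <- cumsum(counts)
  log <- data.frame(cell_order = seq_len(n_cells), count = counts,
                    cumulative = cum)
  if (nrow(ok) < min_n) {
    warning(sprintf("only %d annotations available (< %d); returning all",
                    nrow(ok), min_n))
    stop_at <- n_cells
  } else {
    stop_at <- which(cum >= min_n)[1]
  }
  sel <- ok[ok$cell_order <= stop_at, , drop = FALSE]
  list(labels = sel$label, n_selected = nrow(sel),
       cells_used = stop_at, log = log)
}
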