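# Internal helpers shared across modules.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
# Every generator routes its randomness through this, so outputs are pure
# functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sample standard deviation (n - 1 denominator); NA for n < 2.
sample_sd <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)

#' Adjusted Fisher-Pearson skewness
#'
#' Standardized third central moment with the small-sample adjustment
#' `sqrt(n (n - 1)) / (n - 2)`, matching the default of mainstream
#' statistical software. Returns `NA` for fewer than 3 values or zero
#' variance.
#'
#' @param x Numeric vector.
#' @return Skewness estimate (length-1 numeric).
#' @export
skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Rasterize one polygon (continuous 0-based x = column / y = row coordinates)
# onto a height x width pixel grid: a pixel belongs to the polygon iff its
# center (x = col - 1, y = row - 1) lies inside or on the boundary.
# Returns an n x 2 matrix of (row, col) 1-based pixel indices.
rasterize_polygon_pixels <- function(vertices, width_px, height_px) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  c0 <- max(1L, floor(min(vx)) + 1L); c1 <- min(width_px,  ceiling(max(vx)) + 1L)
  r0 <- max(1L, floor(min(vy)) + 1L); r1 <- min(height_px, ceiling(max(vy)) + 1L)
  if (c0 > c1 || r0 > r1) return(matrix(integer(0), 0, 2))
  cols <- c0:c1; rows <- r0:r1
  g <- expand.grid(row = rows, col = cols)
  inside <- pracma::inpolygon(g$col - 1, g$row - 1, vx, vy, boundary = TRUE)
  as.matrix(g[inside, c("row", "col"), drop = FALSE])
}

#' Rasterize labeled polygons to an instance label mask
#'
#' Pixel-center convention: pixel (row, col) of the mask has continuous
#' coordinates (x, y) = (col - 1, row - 1). Pixels on the polygon boundary are
#' included. When polygons overlap, the later polygon in the list wins,
#' mirroring how overlapping nuclei merge in a binary segmentation.
#'
#' @param polygons List of `list(label =, vertices =)` entries, vertices an
#'   n x 2 matrix of (x, y) coordinates.
#' @param width_px,height_px Output mask size in pixels.
#' @return Integer matrix (`height_px` x `width_px`) of instance labels,
#'   0 = background.
#' @export
rasterize_polygons <- function(polygons, width_px, height_px) {
  mask <- matrix(0L, height_px, width_px)
  for (p in polygons) {
    px <- rasterize_polygon_pixels(p$vertices, width_px, height_px)
    if (nrow(px)) mask[cbind(px[, 1], px[, 2])] <- as.integer(p$label)
  }
  mask
}

stopifnot_binary_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop("expected a binary {0,1} mask matrix")
  invisible(TRUE)
}

mask_resolution <- function(mask, default = NA_real_) {
  r <- attr(mask, "resolution_um_per_px")
  if (is.null(r)) default else r
}
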