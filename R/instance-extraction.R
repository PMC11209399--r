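# Binary mask -> measured nucleus instances: connected-component labeling,
# pixel-to-area unit conversion, and the small-object noise filter.

#' Connected-component labeling of a binary mask
#'
#' Maximal connected foreground sets under 4- or 8-connectivity, computed by
#' iterative minimum-label propagation (vectorized over the whole grid until
#' a fixed point). Labels are renumbered 1..K in order of each component's
#' first pixel in column-major scan order, so the labeling is deterministic.
#'
#' @param mask Binary 0/1 matrix.
#' @param connectivity 8 (default, diagonal neighbors connect) or 4.
#' @return Integer label matrix, 0 = background, labels 1..K contiguous;
#'   carries over a `resolution_um_per_px` attribute if present on `mask`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot_binary_mask(unclass_attr(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  fg <- mask > 0
  lab <- matrix(0, H, W)
  lab[fg] <- which(fg)  # provisional label = linear index
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  pad <- matrix(Inf, H + 2, W + 2)
  repeat {
    pad[] <- Inf
    pad[2:(H + 1), 2:(W + 1)] <- ifelse(fg, lab, Inf)
    m <- lab
    for (s in shifts) {
      nb <- pad[(2 + s[1]):(H + 1 + s[1]), (2 + s[2]):(W + 1 + s[2])]
      m <- pmin(m, nb)
    }
    m[!fg] <- 0
    if (identical(m, lab)) break
    lab <- m
  }
  out <- matrix(0L, H, W)
  if (any(fg)) {
    ids <- lab[fg]
    first <- sort(unique(ids))
    # order components by first occurrence (min linear index = the id itself)
    remap <- integer(0); remap[first] <- seq_along(first)
    out[fg] <- remap[ids]
  }
  r <- attr(mask, "resolution_um_per_px")
  if (!is.null(r)) attr(out, "resolution_um_per_px") <- r
  out
}

# strip non-dim attributes so stopifnot_binary_mask sees a plain matrix
unclass_attr <- function(m) {
  x <- as.matrix(m)
  attributes(x) <- list(dim = dim(x))
  x
}

#' Convert a pixel count to an area in square microns
#'
#' `area = pixel_count * resolution^2`.
#'
#' @param pixel_count Non-negative pixel count(s).
#' @param resolution_um_per_px Scan resolution (> 0).
#' @return Area(s) in um^2.
#' @export
pixels_to_area <- function(pixel_count, resolution_um_per_px) {
  if (any(resolution_um_per_px <= 0)) stop("resolution must be positive")
  pixel_count * resolution_um_per_px^2
}

#' Extract nucleus instances from a label mask
#'
#' Builds the per-instance table (pixel count, area in um^2, centroid) and
#' retains each instance's pixel coordinates for shape measurement. Instances
#' touching the image border are retained by default; `exclude_border = TRUE`
#' drops them (the manual protocol excludes margin-cut nuclei, the automated
#' pipeline does not).
#'
#' @param label_mask Integer instance label mask (0 = background).
#' @param resolution_um_per_px Scan resolution; taken from the mask attribute
#'   if omitted.
#' @param exclude_border Drop instances with a pixel on the image border.
#' @return Object of class `nucleus_instances`: a data frame with columns
#'   `label`, `pixel_count`, `area_um2`, `centroid_row`, `centroid_col`, and
#'   attributes `pixels` (list of n x 2 (row, col) matrices) and
#'   `resolution_um_per_px`.
#' @export
extract_instances <- function(label_mask, resolution_um_per_px = NULL,
                              exclude_border = FALSE) {
  res <- if (is.null(resolution_um_per_px))
    mask_resolution(label_mask) else resolution_um_per_px
  if (is.na(res)) stop("resolution_um_per_px is required")
  idx <- which(label_mask > 0)
  labs <- label_mask[idx]
  rows <- ((idx - 1) %% nrow(label_mask)) + 1
  cols <- ((idx - 1) %/% nrow(label_mask)) + 1
  ord <- sort(unique(labs))
  pixels <- lapply(ord, function(k) {
    sel <- labs == k
    cbind(row = rows[sel], col = cols[sel])
  })
  if (exclude_border && length(ord)) {
    keep <- vapply(pixels, function(p)
      !any(p[, 1] == 1 | p[, 1] == nrow(label_mask) |
           p[, 2] == 1 | p[, 2] == ncol(label_mask)), logical(1))
    ord <- ord[keep]; pixels <- pixels[keep]
  }
  df <- data.frame(
    label = as.integer(ord),
    pixel_count = vapply(pixels, nrow, integer(1)),
    centroid_row = vapply(pixels, function(p) mean(p[, 1]), numeric(1)),
    centroid_col = vapply(pixels, function(p) mean(p[, 2]), numeric(1)))
  df$area_um2 <- pixels_to_area(df$pixel_count, res)
  df <- df[, c("label", "pixel_count", "area_um2",
               "centroid_row", "centroid_col")]
  structure(df, pixels = pixels, resolution_um_per_px = res,
            class = c("nucleus_instances", "data.frame"))
}

#' Filter out sub-nuclear noise objects
#'
#' Removes instances with `area_um2 < min_area_um2` (strict inequality, so an
#' object of exactly the threshold area is retained). Original labels are
#' preserved.
#'
#' @param instances A `nucleus_instances` object (or data frame with
#'   `area_um2`).
#' @param min_area_um2 Minimum area in um^2; default 7, the noise floor below
#'   which detected objects are considered too small to be nuclei.
#' @return Filtered object of the same class.
#' @export
filter_small_objects <- function(instances, min_area_um2 = 7.0) {
  keep <- instances$area_um2 >= min_area_um2
  out <- instances[keep, , drop = FALSE]
  px <- attr(instances, "pixels")
  if (!is.null(px)) attr(out, "pixels") <- px[keep]
  attr(out, "resolution_um_per_px") <- attr(instances, "resolution_um_per_px")
  class(out) <- class(instances)
  rownames(out) <- NULL
  out
}

#' Rasterize instances back to a label mask
#'
#' Inverse of [extract_instances()]: writes each instance's pixels back to a
#' label matrix.
#'
#' @param instances A `nucleus_instances` object.
#' @param width_px,height_px Output size.
#' @return Integer label matrix.
#' @export
rasterize_instances <- function(instances, width_px, height_px) {
  out <- matrix(0L, height_px, width_px)
  px <- attr(instances, "pixels")
  for (i in seq_along(px))
    out[px[[i]]] <- instances$label[i]
  r <- attr(instances, "resolution_um_per_px")
  if (!is.null(r)) attr(out, "resolution_um_per_px") <- r
  out
}
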