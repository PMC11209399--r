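# Per-instance shape descriptors (area, eccentricity, solidity) and the
# per-ROI morphometric parameter profile.

#' Karyomegaly area thresholds
#'
#' Two fixed nuclear-size cutoffs used to report the percentage of large
#' (karyomegalic) nuclei. The defaults, 42.3 and 50.5 um^2, are the 90th
#' percentile and twice the median of the nuclear areas of a large annotated
#' reference set of tumor nuclei.
#'
#' @param p90_um2 First threshold (um^2).
#' @param twice_median_um2 Second threshold (um^2).
#' @return Object of class `karyomegaly_thresholds`.
#' @export
karyomegaly_thresholds <- function(p90_um2 = 42.3, twice_median_um2 = 50.5) {
  stopifnot(p90_um2 > 0, twice_median_um2 > 0)
  structure(list(p90_um2 = p90_um2, twice_median_um2 = twice_median_um2),
            class = "karyomegaly_thresholds")
}

#' Derive karyomegaly thresholds from a reference area distribution
#'
#' Computes (90th percentile, 2 x median) of the supplied reference nuclear
#' areas; with no reference the package defaults (42.3, 50.5 um^2) are
#' returned. Percentiles use linear interpolation between order statistics.
#'
#' @param reference_areas_um2 Optional numeric vector of >= 10 areas.
#' @return A [karyomegaly_thresholds()] object.
#' @export
derive_karyomegaly_thresholds <- function(reference_areas_um2 = NULL) {
  if (is.null(reference_areas_um2)) return(karyomegaly_thresholds())
  if (length(reference_areas_um2) < 10)
    stop("need at least 10 reference areas")
  karyomegaly_thresholds(
    p90_um2 = unname(stats::quantile(reference_areas_um2, 0.9, type = 7)),
    twice_median_um2 = 2 * stats::median(reference_areas_um2))
}

#' Measure one nucleus instance
#'
#' Area from the pixel count and scan resolution; eccentricity from the
#' ellipse matched to the pixel set's second central moments
#' (`sqrt(1 - l2/l1)` with `l1 >= l2` the covariance eigenvalues, each pixel
#' modeled as a unit square so a single pixel has eccentricity 0); solidity
#' as the pixel count divided by the pixel count of the rasterized convex
#' hull of the pixel centers (so a convex rasterized shape has solidity
#' exactly 1).
#'
#' @param pixels n x 2 matrix of (row, col) pixel indices (n >= 1).
#' @param resolution_um_per_px Scan resolution.
#' @return List with `area_um2`, `eccentricity` (in \[0, 1)), `solidity`
#'   (in (0, 1\]).
#' @export
measure_instance <- function(pixels, resolution_um_per_px) {
  n <- nrow(pixels)
  stopifnot(n >= 1, resolution_um_per_px > 0)
  area <- pixels_to_area(n, resolution_um_per_px)
  # eccentricity: covariance of pixel centers + unit-square self-covariance
  if (n == 1L) {
    ecc <- 0
  } else {
    cv <- stats::cov(pixels) * (n - 1) / n + diag(1 / 12, 2)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
    ecc <- min(ecc, 1 - 1e-9)
  }
  list(area_um2 = area, eccentricity = ecc,
       solidity = instance_solidity(pixels))
}

instance_solidity <- function(pixels) {
  n <- nrow(pixels)
  if (n <= 2L) return(1)
  x <- pixels[, 2]; y <- pixels[, 1]
  hull <- grDevices::chull(x, y)
  if (length(hull) < 3L) return(1)  # collinear pixel set
  vx <- x[hull] - 1; vy <- y[hull] - 1  # 0-based continuous coords
  xr <- range(x); yr <- range(y)
  g <- expand.grid(col = xr[1]:xr[2], row = yr[1]:yr[2])
  inside <- pracma::inpolygon(g$col - 1, g$row - 1, vx, vy, boundary = TRUE)
  n / max(sum(inside), n)
}

#' Measure all instances
#'
#' Adds `eccentricity` and `solidity` columns to a `nucleus_instances` table.
#'
#' @param instances A `nucleus_instances` object from [extract_instances()].
#' @return The same object with shape columns appended.
#' @export
measure_instances <- function(instances) {
  px <- attr(instances, "pixels")
  res <- attr(instances, "resolution_um_per_px")
  if (is.null(px)) stop("instances must carry pixel sets")
  shp <- lapply(px, measure_instance, resolution_um_per_px = res)
  out <- instances
  out$eccentricity <- vapply(shp, `[[`, numeric(1), "eccentricity")
  out$solidity <- vapply(shp, `[[`, numeric(1), "solidity")
  attr(out, "pixels") <- px
  attr(out, "resolution_um_per_px") <- res
  class(out) <- class(instances)
  out
}

#' Invert a solidity summary into an irregularity score
#'
#' `1 - solidity`, so that larger values mean more irregular nuclear
#' contours.
#'
#' @param mean_or_median_solidity Value(s) in (0, 1\].
#' @return Irregularity score(s) in \[0, 1).
#' @export
invert_solidity <- function(mean_or_median_solidity) {
  if (any(mean_or_median_solidity <= 0 | mean_or_median_solidity > 1))
    stop("solidity must lie in (0, 1]")
  1 - mean_or_median_solidity
}

#' Per-ROI morphometric parameter profile
#'
#' Summarizes a measured instance table into the standard parameter vector:
#' for nuclear area — mean, median, SD, skewness, mean and median of the
#' largest 10% of nuclei, 90th percentile, and the percentages above the two
#' karyomegaly thresholds; for eccentricity and solidity — mean, median, SD,
#' skewness; plus the inverted-solidity irregularity scores. SDs use the
#' sample (n - 1) denominator; skewness is the adjusted Fisher-Pearson
#' estimate; "largest 10%" means the `ceiling(0.1 n)` largest instances;
#' percentiles interpolate linearly between order statistics. SD and
#' skewness are `NA` when fewer than 2 (respectively 3) instances are
#' present.
#'
#' @param instances A measured `nucleus_instances` table (see
#'   [measure_instances()]).
#' @param thresholds A [karyomegaly_thresholds()] object.
#' @return One-row data frame; the ROI parameter profile.
#' @export
profile_roi <- function(instances, thresholds = karyomegaly_thresholds()) {
  stopifnot(inherits(thresholds, "karyomegaly_thresholds"))
  a <- instances$area_um2
  e <- instances$eccentricity
  s <- instances$solidity
  if (is.null(e) || is.null(s))
    stop("instances must be measured (eccentricity/solidity missing); ",
         "see measure_instances()")
  n <- length(a)
  if (n == 0L) stop("no instances to profile")
  top <- sort(a, decreasing = TRUE)[seq_len(ceiling(0.1 * n))]
  data.frame(
    n_instances = n,
    area_mean = mean(a), area_median = stats::median(a),
    area_sd = sample_sd(a), area_skew = skewness(a),
    area_top10_mean = mean(top), area_top10_median = stats::median(top),
    area_p90 = unname(stats::quantile(a, 0.9, type = 7)),
    area_pct_above_thr90 = 100 * mean(a > thresholds$p90_um2),
    area_pct_above_thr2med = 100 * mean(a > thresholds$twice_median_um2),
    thr90_um2 = thresholds$p90_um2,
    thr2med_um2 = thresholds$twice_median_um2,
    ecc_mean = mean(e), ecc_median = stats::median(e),
    ecc_sd = sample_sd(e), ecc_skew = skewness(e),
    sol_mean = mean(s), sol_median = stats::median(s),
    sol_sd = sample_sd(s), sol_skew = skewness(s),
    irregularity_mean = invert_solidity(mean(s)),
    irregularity_median = invert_solidity(stats::median(s)))
}
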