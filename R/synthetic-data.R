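# Seeded generators for nucleus images with exact ground truth, survival
# cohorts with known hazard structure, and multi-rater ordinal panels.

#' Specification of a synthetic H&E-like ROI image
#'
#' Describes a rectangular region of interest densely populated with
#' elliptical tumor nuclei. Defaults emulate a 0.1185 mm^2 region at
#' 0.25 um/pixel (a 4:3 field of 1590 x 1192 px) with a log-normal nuclear
#' area law (mean 30, SD 10 um^2) so that anisokaryosis, contour
#' irregularity and nuclear overlap are all independently controllable.
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param resolution_um_per_px Scan resolution (um per pixel edge).
#' @param n_nuclei Number of nuclei to place.
#' @param area_mean_um2,area_sd_um2 Mean and SD of the log-normal nuclear
#'   area distribution, in um^2. `area_mean_um2` must exceed the 7 um^2
#'   noise-filter floor.
#' @param axis_ratio_range Range of the uniform major/minor axis-ratio law;
#'   must lie within \[1, 4\].
#' @param irregularity Radial contour-noise amplitude in \[0, 1\], as a
#'   fraction of the mean radius.
#' @param overlap_fraction Fraction of placements allowed to intersect a
#'   previously placed nucleus, in \[0, 1\]. With 0, instances are pairwise
#'   disjoint.
#' @param stain_palette List with `fg`, `bg` (RGB means in \[0, 1\]) and
#'   `noise_sd` controlling the rendered contrast.
#' @param seed Integer seed; part of the spec, so identical specs give
#'   bit-identical fixtures.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(width_px = 1590L, height_px = 1192L,
                       resolution_um_per_px = 0.25,
                       n_nuclei = 600L,
                       area_mean_um2 = 30, area_sd_um2 = 10,
                       axis_ratio_range = c(1, 2.5),
                       irregularity = 0.1,
                       overlap_fraction = 0,
                       stain_palette = list(
                         fg = c(0.38, 0.26, 0.55),
                         bg = c(0.92, 0.88, 0.94),
                         noise_sd = 0.03),
                       seed = 1L) {
  stopifnot(width_px > 0, height_px > 0, resolution_um_per_px > 0,
            n_nuclei >= 0, area_sd_um2 >= 0,
            irregularity >= 0, irregularity <= 1,
            overlap_fraction >= 0, overlap_fraction <= 1)
  if (area_mean_um2 <= 7)
    stop("area_mean_um2 must exceed the 7 um^2 noise floor")
  if (axis_ratio_range[1] < 1 || axis_ratio_range[2] > 4 ||
      diff(axis_ratio_range) < 0)
    stop("axis_ratio_range must be an increasing range within [1, 4]")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 resolution_um_per_px = resolution_um_per_px,
                 n_nuclei = as.integer(n_nuclei),
                 area_mean_um2 = area_mean_um2, area_sd_um2 = area_sd_um2,
                 axis_ratio_range = axis_ratio_range,
                 irregularity = irregularity,
                 overlap_fraction = overlap_fraction,
                 stain_palette = stain_palette,
                 seed = as.integer(seed)),
            class = "image_spec")
}

# Contour of one nucleus: ellipse with low-order radial Fourier perturbation.
# Returns an n_vertices x 2 matrix of (x, y) coordinates.
nucleus_polygon <- function(center, area_px2, axis_ratio, angle, irregularity,
                            n_vertices = 64L) {
  a <- sqrt(area_px2 * axis_ratio / pi)  # semi-major (px)
  b <- a / axis_ratio
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  delta <- 0
  if (irregularity > 0) {
    k <- 2:5
    amp <- stats::rnorm(length(k))
    ph <- stats::runif(length(k), 0, 2 * pi)
    wave <- colSums(amp * sin(outer(k, phi) + ph))
    m <- max(abs(wave), 1e-9)
    r_mean <- (a + b) / 2
    delta <- irregularity * r_mean * wave / m  # max |delta| = irr * r_mean
  }
  ex <- a * cos(phi); ey <- b * sin(phi)
  # radial perturbation along the local outward normal direction of the circle
  # parameterization, applied before rotation
  rr <- sqrt(ex^2 + ey^2)
  scale <- pmax(1 + delta / rr, 0.1)  # keep the contour simple and positive
  ex <- ex * scale; ey <- ey * scale
  xs <- center[1] + ex * cos(angle) - ey * sin(angle)
  ys <- center[2] + ex * sin(angle) + ey * cos(angle)
  cbind(xs, ys)
}

#' Generate a synthetic nucleus image with exact ground truth
#'
#' Places `n_nuclei` perturbed ellipses on the canvas, rasterizes them into an
#' instance label mask (labels 1..K, contiguous), and renders an RGB image
#' with darker-stained foreground. Rasterizing the returned polygons with
#' [rasterize_polygons()] reproduces the returned mask exactly when
#' `overlap_fraction = 0`. Placement is by bounded rejection sampling; if a
#' nucleus cannot be placed disjointly after `max_tries` attempts it is
#' skipped and the shortfall reported via the `n_requested` field and a
#' warning.
#'
#' @param spec An [image_spec()].
#' @param max_tries Placement attempts per nucleus before giving up.
#' @return List of class `nucmorph_roi` with elements `image` (height x width
#'   x 3 array in \[0, 1\]), `mask` (integer label matrix with
#'   `resolution_um_per_px` attribute), `polygons` (list of
#'   `list(label, vertices)`, 0-based pixel coordinates, x = column),
#'   `n_placed`, `n_requested`, and `spec`.
#' @export
generate_nucleus_image <- function(spec, max_tries = 200L) {
  stopifnot(inherits(spec, "image_spec"))
  with_seed(spec$seed, {
    W <- spec$width_px; H <- spec$height_px; res <- spec$resolution_um_per_px
    # log-normal area law parameterized by mean/sd in um^2
    s2 <- log(1 + (spec$area_sd_um2 / spec$area_mean_um2)^2)
    mu <- log(spec$area_mean_um2) - s2 / 2
    polys <- vector("list", spec$n_nuclei)
    centers <- matrix(NA_real_, spec$n_nuclei, 2)
    radii <- numeric(spec$n_nuclei)
    placed <- 0L
    for (i in seq_len(spec$n_nuclei)) {
      area_um2 <- stats::rlnorm(1, mu, sqrt(s2))
      area_px2 <- area_um2 / res^2
      q <- stats::runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
      ang <- stats::runif(1, 0, pi)
      a <- sqrt(area_px2 * q / pi)
      rmax <- a * (1 + spec$irregularity) + 1  # conservative outer radius
      allow_overlap <- spec$overlap_fraction > 0 &&
        stats::runif(1) < spec$overlap_fraction
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- stats::runif(1, rmax + 1, W - rmax - 2)
        cy <- stats::runif(1, rmax + 1, H - rmax - 2)
        if (allow_overlap || placed == 0L) { ok <- TRUE; break }
        d <- sqrt((centers[seq_len(placed), 1] - cx)^2 +
                  (centers[seq_len(placed), 2] - cy)^2)
        if (all(d > radii[seq_len(placed)] + rmax + 1.5)) { ok <- TRUE; break }
      }
      if (!ok) next
      placed <- placed + 1L
      centers[placed, ] <- c(cx, cy)
      radii[placed] <- rmax
      polys[[placed]] <- list(
        label = placed,
        vertices = nucleus_polygon(c(cx, cy), area_px2, q, ang,
                                   spec$irregularity))
    }
    polys <- polys[seq_len(placed)]
    if (placed < spec$n_nuclei)
      warning(sprintf("placed %d of %d nuclei (canvas too crowded)",
                      placed, spec$n_nuclei))
    mask <- rasterize_polygons(polys, W, H)
    # relabel contiguously in case an overlapping polygon fully covered an
    # earlier one
    labs <- sort(unique(mask[mask > 0]))
    if (length(labs) && !identical(labs, seq_along(labs))) {
      remap <- integer(max(labs)); remap[labs] <- seq_along(labs)
      mask[mask > 0] <- remap[mask[mask > 0]]
      polys <- polys[labs]
      for (j in seq_along(polys)) polys[[j]]$label <- j
    }
    attr(mask, "resolution_um_per_px") <- res
    pal <- spec$stain_palette
    img <- array(0, c(H, W, 3))
    fg <- mask > 0
    for (ch in 1:3) {
      plane <- matrix(pal$bg[ch], H, W)
      plane[fg] <- pal$fg[ch]
      plane <- plane + stats::rnorm(H * W, 0, pal$noise_sd)
      img[, , ch] <- pmin(1, pmax(0, plane))
    }
    structure(list(image = img, mask = mask, polygons = polys,
                   n_placed = placed, n_requested = spec$n_nuclei,
                   spec = spec),
              class = "nucmorph_roi")
  })
}

#' @export
print.nucmorph_roi <- function(x, ...) {
  cat(sprintf("<nucmorph_roi> %d x %d px @ %.3g um/px, %d/%d nuclei placed\n",
              x$spec$width_px, x$spec$height_px,
              x$spec$resolution_um_per_px, x$n_placed, x$n_requested))
  invisible(x)
}

#' Specification of a synthetic survival cohort
#'
#' Proportional-hazards cohort with an exponential baseline hazard,
#' case-level covariates with known log-hazard coefficients, uniform
#' administrative censoring, and a hard follow-up cap (default 250 days,
#' matching a 250-day tumor-specific survival analysis).
#'
#' @param n_cases Number of cases (>= 2).
#' @param covariates Named list of covariate laws; each entry is
#'   `list(type = "normal"|"lognormal"|"binary", ...)` with parameters
#'   `mean`/`sd` (normal, lognormal: of the underlying normal) or `prob`
#'   (binary).
#' @param coef Named numeric vector of log-hazard coefficients, one per
#'   covariate (names must match `covariates`).
#' @param baseline_rate Exponential baseline hazard rate (events/day), > 0.
#' @param censor_horizon_days Administrative censoring times are drawn
#'   uniformly on \[`censor_horizon_days[1]`, `censor_horizon_days[2]`\].
#' @param followup_cap_days Hard cap on observed time (default 250).
#' @param lost_fraction,other_death_fraction Fractions of cases relabeled as
#'   lost to follow-up / dead of unrelated cause at their censoring time,
#'   emulating real outcome records.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 46L,
                        covariates = list(
                          area_sd = list(type = "lognormal",
                                         mean = log(14), sd = 0.45)),
                        coef = c(area_sd = 0.05),
                        baseline_rate = 1 / 600,
                        censor_horizon_days = c(200, 2000),
                        followup_cap_days = 250L,
                        lost_fraction = 0,
                        other_death_fraction = 0,
                        seed = 1L) {
  stopifnot(n_cases >= 2, baseline_rate > 0, followup_cap_days > 0,
            length(censor_horizon_days) == 2,
            all(censor_horizon_days > 0),
            lost_fraction >= 0, other_death_fraction >= 0,
            lost_fraction + other_death_fraction <= 1)
  if (!setequal(names(covariates), names(coef)))
    stop("covariates and coef must have matching names")
  structure(list(n_cases = as.integer(n_cases), covariates = covariates,
                 coef = coef, baseline_rate = baseline_rate,
                 censor_horizon_days = censor_horizon_days,
                 followup_cap_days = as.integer(followup_cap_days),
                 lost_fraction = lost_fraction,
                 other_death_fraction = other_death_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic outcome cohort
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(sum(coef * covariates))`; censoring times are uniform
#' administrative; observed time is capped at `followup_cap_days`. Events
#' observed at the cap boundary are censored there ("alive"). A configurable
#' fraction of censored cases is relabeled "lost" or "other_death" to
#' exercise the cohort-preparation rules.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `case_id`, one column per covariate, `time_days`
#'   and `event` in `c("tumor_death", "other_death", "lost", "alive")`.
#' @export
generate_outcome_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cases
    X <- lapply(names(spec$covariates), function(nm) {
      law <- spec$covariates[[nm]]
      switch(law$type,
        normal = stats::rnorm(n, law$mean, law$sd),
        lognormal = stats::rlnorm(n, law$mean, law$sd),
        binary = stats::rbinom(n, 1, law$prob),
        stop("unknown covariate law type: ", law$type))
    })
    names(X) <- names(spec$covariates)
    lp <- Reduce(`+`, Map(function(x, b) x * b,
                          X, as.list(spec$coef[names(X)])), 0)
    t_event <- stats::rexp(n, spec$baseline_rate * exp(lp))
    t_cens <- stats::runif(n, spec$censor_horizon_days[1],
                           spec$censor_horizon_days[2])
    cap <- spec$followup_cap_days
    time <- pmin(t_event, t_cens, cap)
    event_obs <- t_event <= pmin(t_cens, cap) & t_event < cap
    status <- ifelse(event_obs, "tumor_death", "alive")
    # relabel a deterministic-by-seed subset of the censored cases
    cens_idx <- which(!event_obs)
    n_lost <- round(spec$lost_fraction * n)
    n_other <- round(spec$other_death_fraction * n)
    if (n_lost + n_other > 0 && length(cens_idx)) {
      pick <- sample(cens_idx, min(length(cens_idx), n_lost + n_other))
      if (n_lost > 0) status[pick[seq_len(min(n_lost, length(pick)))]] <- "lost"
      if (n_other > 0 && length(pick) > n_lost)
        status[pick[(n_lost + 1):length(pick)]] <- "other_death"
    }
    if (!any(event_obs)) warning("degenerate censoring: no events observed")
    out <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                      time_days = time, event = status,
                      stringsAsFactors = FALSE)
    for (nm in names(X)) out[[nm]] <- X[[nm]]
    out
  })
}

#' Specification of a multi-rater ordinal estimate panel
#'
#' Each rater converts a latent continuous score (e.g., the SD of nuclear
#' area of a case) into an ordinal category by thresholding at personal
#' cutpoints after adding personal noise — emulating how different
#' pathologists map the same morphology onto different grade categories.
#'
#' @param n_raters Number of raters (>= 2).
#' @param cutpoints Either a numeric vector (shared by all raters) or a list
#'   of length `n_raters`; each must be strictly increasing with
#'   `n_categories - 1` values.
#' @param noise_sd Per-rater noise SD (scalar recycled, or vector).
#' @param n_categories Number of ordinal categories (3 for anisokaryosis,
#'   2 for shape irregularity).
#' @param seed Integer seed.
#' @return Object of class `rater_spec`.
#' @export
rater_spec <- function(n_raters = 11L, cutpoints = c(10, 20), noise_sd = 0,
                       n_categories = length(cutpoints) + 1L, seed = 1L) {
  stopifnot(n_raters >= 2, n_categories >= 2)
  if (!is.list(cutpoints)) cutpoints <- rep(list(cutpoints), n_raters)
  if (length(cutpoints) != n_raters)
    stop("need one cutpoint vector per rater")
  for (cp in cutpoints) {
    if (length(cp) != n_categories - 1L || is.unsorted(cp, strictly = TRUE))
      stop("cutpoints must be strictly increasing, n_categories - 1 values")
  }
  noise_sd <- rep_len(noise_sd, n_raters)
  structure(list(n_raters = as.integer(n_raters), cutpoints = cutpoints,
                 noise_sd = noise_sd, n_categories = as.integer(n_categories),
                 seed = as.integer(seed)),
            class = "rater_spec")
}

#' Generate a multi-rater ordinal rating panel
#'
#' @param latent_scores Numeric vector, one latent score per case.
#' @param spec A [rater_spec()].
#' @return Integer matrix (cases x raters) of categories 1..`n_categories`,
#'   with column names `R1..Rk`.
#' @export
generate_rating_panel <- function(latent_scores, spec) {
  stopifnot(inherits(spec, "rater_spec"), length(latent_scores) >= 1)
  with_seed(spec$seed, {
    n <- length(latent_scores)
    out <- matrix(NA_integer_, n, spec$n_raters,
                  dimnames = list(NULL, paste0("R", seq_len(spec$n_raters))))
    for (j in seq_len(spec$n_raters)) {
      noisy <- latent_scores + if (spec$noise_sd[j] > 0)
        stats::rnorm(n, 0, spec$noise_sd[j]) else 0
      out[, j] <- 1L + rowSums(outer(noisy, spec$cutpoints[[j]], `>`))
    }
    out
  })
}
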