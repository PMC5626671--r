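# Semi-quantitative measurements: ROI/VOI statistics, hot-rod metrics
# (Hr, BKG, SD, HBR, CNR), sphere-to-background and uptake ratios,
# isocontour-VOI segmentation and threshold calibration, lesion-to-
# background ratio, and count linearity.

#' ROI / VOI specification
#'
#' @param shape "circle" (planar image or a single volume slice) or
#'   "sphere" (volume).
#' @param center mm coordinates: length 2 (x, z) for planar circles,
#'   length 3 for volumes.
#' @param diameter_mm ROI diameter, mm (> 0).
#' @param slice optional slice index for a circle drawn on a volume
#'   transaxial slice.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(shape = c("circle", "sphere"), center, diameter_mm,
                     slice = NULL) {
  shape <- match.arg(shape)
  if (diameter_mm <= 0) stop("ROI diameter must be > 0")
  structure(list(shape = shape, center = as.numeric(center),
                 diameter_mm = diameter_mm, slice = slice),
            class = "roi_spec")
}

# logical membership mask for an roi_spec on a planar image or voxel grid
.roi_mask <- function(image, roi) {
  r2 <- (roi$diameter_mm / 2)^2
  if (inherits(image, "planar_image")) {
    stopifnot(roi$shape == "circle", length(roi$center) == 2)
    d <- dim(image$values)
    xs <- image$origin[1] + (seq_len(d[1]) - 0.5) * image$pixel_size[1]
    zs <- image$origin[2] + (seq_len(d[2]) - 0.5) * image$pixel_size[2]
    if (roi$center[1] < min(xs) || roi$center[1] > max(xs) ||
        roi$center[2] < min(zs) || roi$center[2] > max(zs))
      stop("ROI centre lies outside the image")
    outer((xs - roi$center[1])^2, (zs - roi$center[2])^2, `+`) <= r2
  } else if (inherits(image, "voxel_grid")) {
    d <- dim(image$values)
    xs <- grid_centers(image, 1); ys <- grid_centers(image, 2)
    zs <- grid_centers(image, 3)
    if (roi$shape == "sphere") {
      stopifnot(length(roi$center) == 3)
      if (any(roi$center < image$origin) ||
          any(roi$center > image$origin + d * image$voxel_size))
        stop("VOI centre lies outside the volume")
      m <- array(FALSE, d)
      dz2 <- (zs - roi$center[3])^2
      inplane <- outer((xs - roi$center[1])^2, (ys - roi$center[2])^2, `+`)
      for (k in seq_len(d[3])) m[, , k] <- inplane + dz2[k] <= r2
      m
    } else {
      stopifnot(!is.null(roi$slice), length(roi$center) >= 2)
      if (roi$slice < 1 || roi$slice > d[3]) stop("slice index out of range")
      m <- array(FALSE, d)
      m[, , roi$slice] <-
        outer((xs - roi$center[1])^2, (ys - roi$center[2])^2, `+`) <= r2
      m
    }
  } else stop("image must be a planar_image or voxel_grid")
}

.region_values <- function(image, region) {
  if (inherits(region, "roi_spec")) region <- .roi_mask(image, region)
  vals <- if (inherits(image, "planar_image")) image$values else image$values
  if (!identical(dim(region), dim(vals)))
    stop("region mask does not match image dimensions")
  if (!any(region)) stop("region captures zero pixels")
  vals[region]
}

#' Mean, SD and pixel count over an ROI
#'
#' Pixels/voxels belong to the ROI iff their centre lies inside it.
#'
#' @param image a `planar_image` or [voxel_grid].
#' @param roi an [roi_spec] or a logical mask of matching dimensions.
#' @return list with `mean`, `sd`, `n`.
#' @export
roi_stats <- function(image, roi) {
  v <- .region_values(image, roi)
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Hot-rod image-quality metrics on a transaxial slice
#'
#' `Hr` is the mean count in the hot-rod ROI; `BKG` the mean of the
#' background-ROI means; `SD` the sample standard deviation (n-1) of those
#' means; `HBR = Hr/BKG`; `CNR = (Hr - BKG)/SD`.
#'
#' @param image a `planar_image` or [voxel_grid] slice view.
#' @param rod_roi [roi_spec] for the hot rod.
#' @param background_rois list of >= 2 background [roi_spec]s.
#' @return object of class `metric_set`: list Hr, BKG, SD, HBR, CNR.
#' @export
hot_metrics <- function(image, rod_roi, background_rois) {
  if (length(background_rois) < 2)
    stop("at least two background ROIs are required")
  hr <- roi_stats(image, rod_roi)$mean
  bmeans <- vapply(background_rois,
                   function(r) roi_stats(image, r)$mean, numeric(1))
  bkg <- mean(bmeans)
  sdv <- stats::sd(bmeans)
  if (bkg == 0) stop("background mean is zero; HBR undefined")
  if (sdv == 0) stop("background ROI means are identical; CNR undefined")
  structure(list(Hr = hr, BKG = bkg, SD = sdv, HBR = hr / bkg,
                 CNR = (hr - bkg) / sdv),
            class = "metric_set")
}

#' Isocontour VOI at a fraction of the regional maximum
#'
#' Voxels inside the search region with value `>= threshold_frac * regional
#' maximum` (closed threshold), restricted to the 6-connected component
#' containing the maximum voxel.
#'
#' @param volume a [voxel_grid].
#' @param search_region logical array (same dims) or an [roi_spec].
#' @param threshold_frac fraction of the regional maximum, in (0, 1].
#' @return list with `mask` (logical array), `volume_cm3`, `threshold`,
#'   `max_value`, `threshold_frac`.
#' @export
isocontour_voi <- function(volume, search_region, threshold_frac) {
  stopifnot(inherits(volume, "voxel_grid"),
            threshold_frac > 0, threshold_frac <= 1)
  if (inherits(search_region, "roi_spec"))
    search_region <- .roi_mask(volume, search_region)
  if (!any(search_region)) stop("search region is empty")
  vals <- volume$values
  vmax <- max(vals[search_region])
  if (vmax <= 0 && min(vals[search_region]) == vmax)
    stop("search region is flat at zero; isocontour undefined")
  thr <- threshold_frac * vmax
  cand <- search_region & vals >= thr
  seed <- which(search_region & vals == vmax)[1]
  mask <- .connected_component(cand, seed)
  list(mask = mask, volume_cm3 = sum(mask) * voxel_volume_ml(volume),
       threshold = thr, max_value = vmax, threshold_frac = threshold_frac)
}

# 6-connected component of `cand` containing linear index `seed`
.connected_component <- function(cand, seed) {
  d <- dim(cand)
  visited <- array(FALSE, d)
  visited[seed] <- TRUE
  frontier <- seed
  nxy <- d[1] * d[2]
  while (length(frontier)) {
    idx <- frontier
    k <- (idx - 1) %/% nxy
    rem <- (idx - 1) %% nxy
    j <- rem %/% d[1]
    i <- rem %% d[1]
    nb <- c(idx[i > 0] - 1, idx[i < d[1] - 1] + 1,
            idx[j > 0] - d[1], idx[j < d[2] - 1] + d[1],
            idx[k > 0] - nxy, idx[k < d[3] - 1] + nxy)
    nb <- unique(nb)
    nb <- nb[cand[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited & cand
}

#' Choose the isocontour threshold that best matches the true volume
#'
#' Given measured isocontour-VOI volumes at candidate thresholds for one or
#' more conditions (e.g. collimators), returns the candidate minimizing the
#' summed absolute volume error against the true volume; ties resolve to
#' the lower threshold.
#'
#' @param volume_sets named list; each element a named numeric vector of
#'   measured volumes (cm^3) keyed by candidate threshold (percent, as
#'   character names).
#' @param true_volume_cm3 true object volume, cm^3.
#' @param candidates candidate thresholds in percent of the maximum.
#' @return chosen threshold (percent), with attribute `errors` holding the
#'   summed absolute errors per candidate.
#' @export
calibrate_threshold <- function(volume_sets, true_volume_cm3,
                                candidates = c(50, 60, 70, 80)) {
  if (!length(volume_sets)) stop("no volume sets supplied")
  key <- as.character(candidates)
  errs <- vapply(key, function(k) {
    sum(vapply(volume_sets, function(vs) {
      if (!k %in% names(vs))
        stop("candidate ", k, "% missing from a volume set")
      abs(vs[[k]] - true_volume_cm3)
    }, numeric(1)))
  }, numeric(1))
  chosen <- candidates[which.min(errs)]   # which.min takes the first (lowest)
  structure(chosen, errors = errs)
}

#' Sphere-to-background ratio
#'
#' Sphere mean divided by the mean of the background-region means. The
#' per-background-region ratios are returned as well so paired comparisons
#' (planar vs SPECT, MEGP vs HEGP) can be run across background positions.
#'
#' @param image a `planar_image` or [voxel_grid].
#' @param sphere_region [roi_spec] or logical mask for the sphere.
#' @param background_regions list of [roi_spec]s or masks.
#' @return list with `sbr`, `sphere_mean`, `background_means`, `per_background`.
#' @export
sbr <- function(image, sphere_region, background_regions) {
  sm <- mean(.region_values(image, sphere_region))
  bm <- vapply(background_regions,
               function(r) mean(.region_values(image, r)), numeric(1))
  if (mean(bm) <= 0) stop("background mean is zero; SBR undefined")
  list(sbr = sm / mean(bm), sphere_mean = sm, background_means = bm,
       per_background = sm / bm)
}

#' Uptake ratio of two regions
#'
#' @param image a `planar_image` or [voxel_grid].
#' @param region1,region2 [roi_spec]s or logical masks (for SPECT the 60%
#'   isocontour masks of the two spheres).
#' @return region-1 mean divided by region-2 mean.
#' @export
uptake_ratio <- function(image, region1, region2) {
  m1 <- mean(.region_values(image, region1))
  m2 <- mean(.region_values(image, region2))
  if (m2 == 0) stop("denominator region mean is zero")
  m1 / m2
}

#' Lesion-to-background ratio with inclusion rule
#'
#' The lesion VOI is the isocontour (default 60% of the regional maximum)
#' within the search region; the background is a spherical VOI (50 cm^3 by
#' default) in the designated background compartment. A lesion is included
#' only if its regional maximum is at least `inclusion_factor` times the
#' normal-reference mean; exclusion is reported, not raised.
#'
#' @param volume a [voxel_grid].
#' @param lesion_search_region logical mask or [roi_spec].
#' @param background_voi [roi_spec] (sphere) or logical mask.
#' @param reference_mean mean count of the normal-reference region (NULL
#'   skips the inclusion rule).
#' @param inclusion_factor multiple of the reference mean required.
#' @param threshold_frac isocontour fraction.
#' @return list with `included`, `lbr` (NA when excluded), `lesion_mean`,
#'   `background_mean`, `voi_volume_cm3`, `max_value`.
#' @export
lbr <- function(volume, lesion_search_region, background_voi,
                reference_mean = NULL, inclusion_factor = 2,
                threshold_frac = 0.6) {
  iso <- isocontour_voi(volume, lesion_search_region, threshold_frac)
  bmean <- mean(.region_values(volume, background_voi))
  if (bmean <= 0) stop("background VOI mean is zero; LBR undefined")
  included <- is.null(reference_mean) ||
    iso$max_value >= inclusion_factor * reference_mean
  lmean <- mean(volume$values[iso$mask])
  list(included = included,
       lbr = if (included) lmean / bmean else NA_real_,
       lesion_mean = lmean, background_mean = bmean,
       voi_volume_cm3 = iso$volume_cm3, max_value = iso$max_value)
}

#' Radius of a sphere with a given volume
#' @param volume_cm3 volume in cm^3.
#' @return radius in mm.
#' @export
sphere_radius_mm <- function(volume_cm3) (3 * volume_cm3 / (4 * pi))^(1 / 3) * 10

#' Count linearity against activity concentration
#'
#' Ordinary least-squares fit of reconstructed mean counts against true
#' activity concentration, with the Pearson correlation.
#'
#' @param concentrations kBq/mL, length >= 3.
#' @param counts matched reconstructed mean counts.
#' @return list with `slope`, `intercept`, `r`, `concentrations`, `counts`.
#' @export
linearity <- function(concentrations, counts) {
  if (length(concentrations) < 3 || length(counts) != length(concentrations))
    stop("need >= 3 matched (concentration, count) pairs")
  if (stats::sd(concentrations) == 0)
    stop("concentrations are constant; fit is degenerate")
  fit <- stats::lm(counts ~ concentrations)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(concentrations, counts),
       concentrations = concentrations, counts = counts)
}
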