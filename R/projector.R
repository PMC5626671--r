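# Forward projection of voxel phantoms into planar statics and SPECT
# projection sets. The in-plane geometry is handled by cached sparse
# bilinear rotation operators so that simulation and reconstruction share
# one exactly-adjoint geometric model.

.ra223_cache <- new.env(parent = emptyenv())

# Sparse bilinear rotation operator on an n x n in-plane grid (centered).
# Maps a flattened image to the image resampled in a frame rotated by
# `angle_deg`; values falling outside the grid are dropped (zero padding).
.rotation_operator <- function(n, angle_deg) {
  key <- sprintf("rot_%d_%.6f", n, angle_deg %% 360)
  hit <- .ra223_cache[[key]]
  if (!is.null(hit)) return(hit)
  th <- angle_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  ctr <- (n + 1) / 2
  xp <- rep(seq_len(n) - ctr, times = n)     # output x' (fast index)
  yp <- rep(seq_len(n) - ctr, each = n)      # output y' (depth, slow index)
  xs <- cs * xp - sn * yp + ctr              # source fractional indices
  ys <- sn * xp + cs * yp + ctr
  i0 <- floor(xs); j0 <- floor(ys)
  fx <- xs - i0; fy <- ys - j0
  out <- seq_len(n * n)
  rows <- integer(0); cols <- integer(0); w <- numeric(0)
  for (corner in 1:4) {
    ii <- i0 + (corner == 2 || corner == 4)
    jj <- j0 + (corner == 3 || corner == 4)
    wt <- (if (corner %in% c(2, 4)) fx else 1 - fx) *
          (if (corner %in% c(3, 4)) fy else 1 - fy)
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & wt > 0
    rows <- c(rows, out[ok])
    cols <- c(cols, ii[ok] + (jj[ok] - 1) * n)
    w <- c(w, wt[ok])
  }
  op <- Matrix::sparseMatrix(i = rows, j = cols, x = w, dims = c(n * n, n * n))
  .ra223_cache[[key]] <- op
  op
}

# Dense symmetric 1D Gaussian convolution matrix (zero padding), cached.
.conv_matrix <- function(n, sigma_px) {
  sig <- round(sigma_px, 3)
  if (sig < 1e-3) return(diag(n))
  key <- sprintf("conv_%d_%.3f", n, sig)
  hit <- .ra223_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- max(1L, ceiling(3 * sig))
  k <- stats::dnorm(-r:r, sd = sig)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    src <- idx + o
    ok <- src >= 1 & src <= n
    M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + k[o + r + 1]
  }
  .ra223_cache[[key]] <- M
  M
}

# Separable 2D Gaussian blur of a matrix; pixel sizes may differ per axis.
.blur2d <- function(img, fwhm_mm, px_mm) {
  sig <- fwhm_mm / (2 * sqrt(2 * log(2)))
  A <- .conv_matrix(nrow(img), sig / px_mm[1])
  B <- .conv_matrix(ncol(img), sig / px_mm[2])
  A %*% img %*% t(B)
}

#' Acquisition specification
#'
#' @param mode "planar" or "spect".
#' @param matrix_size detector matrix (pixels per axis).
#' @param pixel_size_mm detector pixel size, mm.
#' @param n_views frames per detector (spect); a dual-head system
#'   contributes `2 * n_views` views 180 degrees apart.
#' @param angular_step_deg gantry step between frames, degrees.
#' @param time_per_view_s acquisition time per frame, s.
#' @param orbit_radius_mm circular-orbit radius (spect) or detector
#'   standoff from the phantom centre (planar), mm.
#' @param collimator collimator name in the detection model.
#' @param window energy-window name in the detection model.
#' @param seed integer master seed for Poisson sampling, or NULL for the
#'   noiseless expectation.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(mode = c("spect", "planar"),
                             matrix_size = 64, pixel_size_mm = 8.8,
                             n_views = 30, angular_step_deg = 6,
                             time_per_view_s = 60,
                             orbit_radius_mm = 250,
                             collimator = "MEGP", window = "w84_20",
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(time_per_view_s > 0, pixel_size_mm > 0, matrix_size >= 2)
  if (mode == "spect" && abs(n_views * angular_step_deg - 180) > 1e-9)
    stop("spect acquisition must cover 180 degrees per detector head ",
         "(n_views * angular_step_deg == 180)")
  structure(list(mode = mode, matrix_size = as.integer(matrix_size),
                 pixel_size_mm = pixel_size_mm, n_views = as.integer(n_views),
                 angular_step_deg = angular_step_deg,
                 time_per_view_s = time_per_view_s,
                 orbit_radius_mm = orbit_radius_mm,
                 collimator = collimator, window = window, seed = seed),
            class = "acquisition_spec")
}

#' Poisson-sample an expectation image
#'
#' Independent Poisson draws per pixel via inverse-CDF sampling
#' (`qpois(u, lambda)` with one uniform per pixel), reproducible under a
#' fixed seed without disturbing the caller's RNG state. Because the
#' uniforms depend only on the seed, two conditions sampled with the same
#' seed share common random numbers: proportional expectations yield
#' comonotone counts, which pairs simulated condition comparisons the way
#' repeated scans of one physical phantom are paired.
#'
#' @param expectation non-negative numeric array of expected counts.
#' @param seed integer seed.
#' @return integer-valued array of counts, same shape.
#' @export
sample_poisson <- function(expectation, seed) {
  if (any(expectation < 0)) stop("expectation must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- expectation
  out[] <- stats::qpois(stats::runif(length(expectation)),
                        lambda = as.vector(expectation))
  out
}

# Expected projection of an in-detector-frame activity/attenuation pair.
# act, mu: arrays [n_u, n_depth, n_z]; depth index increases toward the
# detector. Returns the primary expectation image [n_u, n_z] in counts.
.project_frame <- function(act, mu, model, spec, depth_mm, px_mm,
                           voxvol_ml, depth_step_mm, blur = TRUE,
                           attenuate = TRUE) {
  nd <- dim(act)[2]
  scale <- voxvol_ml * 1000 * .sensitivity(model, spec$collimator, spec$window) *
    spec$time_per_view_s
  proj <- matrix(0, dim(act)[1], dim(act)[3])
  # attenuation path sums from each depth slab to the detector (half-voxel
  # self term), accumulated from the detector side
  path <- matrix(0, dim(act)[1], dim(act)[3])
  step_cm <- depth_step_mm / 10
  for (j in seq(nd, 1L)) {
    slab <- act[, j, ] * scale
    if (attenuate) {
      mu_j <- mu[, j, ]
      slab <- slab * exp(-(path + 0.5 * mu_j * step_cm))
      path <- path + mu_j * step_cm
    }
    if (blur && any(slab != 0)) {
      d <- spec$orbit_radius_mm - depth_mm[j]
      fw <- collimator_fwhm(model, spec$collimator, d)
      slab <- .blur2d(slab, fw, px_mm)
    }
    proj <- proj + slab
  }
  proj
}

# Add the septal-penetration/scatter pedestal to a primary expectation
# image: broad-Gaussian-convolved primaries plus a flat floor, totalling
# primaries * bf/(1-bf).
.add_pedestal <- function(primary, model, collimator, window, px_mm) {
  bf <- .background_fraction(model, collimator, window)
  if (bf <= 0) return(primary)
  ped_cfg <- model$pedestal
  total <- sum(primary)
  broad <- .blur2d(primary, ped_cfg$broad_fwhm_mm, px_mm)
  flat <- total / length(primary)
  primary + (bf / (1 - bf)) *
    (ped_cfg$broad_weight * as.matrix(broad) + ped_cfg$flat_weight * flat)
}

#' Planar static projection of a voxelized phantom
#'
#' Anteroposterior parallel projection: rays run along +y toward a detector
#' anterior to the phantom. Includes Beer-Lambert attenuation, depth-
#' dependent collimator blur, the pedestal background, and Poisson noise
#' when the spec carries a seed.
#'
#' @param activity [voxel_grid] in kBq/mL.
#' @param attenuation [voxel_grid] in 1/cm, same geometry.
#' @param spec an [acquisition_spec] with mode "planar".
#' @param model a [ra223_model()].
#' @return object of class `planar_image`: `values` (counts, x by z),
#'   `expectation`, `pixel_size`, `origin` (mm, x and z axes).
#' @export
project_planar <- function(activity, attenuation, spec, model) {
  stopifnot(inherits(activity, "voxel_grid"), spec$mode == "planar")
  if (!identical(dim(activity$values), dim(attenuation$values)) ||
      any(abs(activity$voxel_size - attenuation$voxel_size) > 1e-9) ||
      any(abs(activity$origin - attenuation$origin) > 1e-9))
    stop("activity and attenuation grids are not aligned")
  px <- c(activity$voxel_size[1], activity$voxel_size[3])
  # detector frame: depth axis is y, detector on the +y (anterior) side
  depth_mm <- grid_centers(activity, 2)
  act <- activity$values
  # depth index must increase toward the detector: flip so the last slab is
  # the most anterior
  expect <- .project_frame(act, attenuation$values, model, spec, depth_mm,
                           px, voxel_volume_ml(activity),
                           activity$voxel_size[2])
  expect <- .add_pedestal(expect, model, spec$collimator, spec$window, px)
  counts <- if (is.null(spec$seed)) expect else sample_poisson(expect, spec$seed)
  structure(list(values = counts, expectation = expect,
                 pixel_size = px,
                 origin = c(activity$origin[1], activity$origin[3]),
                 spec = spec),
            class = "planar_image")
}

#' SPECT projection set of a voxelized phantom
#'
#' Dual-head acquisition on a circular orbit: head 1 covers
#' `0, step, ..., 180-step` degrees and head 2 the opposite angles. Each
#' view obeys the planar projection contract along its own ray direction.
#' Per-view Poisson streams are derived deterministically from the master
#' seed (seed + view index) so earlier views are unchanged when views are
#' appended.
#'
#' @param activity,attenuation aligned [voxel_grid]s; the in-plane (x, y)
#'   dimensions must be square with voxel size equal to the detector pixel
#'   size.
#' @param spec an [acquisition_spec] with mode "spect".
#' @param model a [ra223_model()].
#' @return object of class `projection_set`: list of `views` (each with
#'   `angle`, `counts`, `expectation`), plus geometry and the spec.
#' @export
project_spect <- function(activity, attenuation, spec, model) {
  stopifnot(inherits(activity, "voxel_grid"), spec$mode == "spect")
  d <- dim(activity$values)
  if (d[1] != d[2] || d[1] != spec$matrix_size)
    stop("spect requires a square in-plane grid matching the detector matrix")
  if (abs(activity$voxel_size[1] - spec$pixel_size_mm) > 1e-9)
    stop("in-plane voxel size must equal the detector pixel size")
  if (!identical(dim(attenuation$values), d))
    stop("activity and attenuation grids are not aligned")
  n <- d[1]; nz <- d[3]
  angles <- c((seq_len(spec$n_views) - 1) * spec$angular_step_deg,
              (seq_len(spec$n_views) - 1) * spec$angular_step_deg + 180)
  px <- c(spec$pixel_size_mm, activity$voxel_size[3])
  depth_mm <- (seq_len(n) - (n + 1) / 2) * spec$pixel_size_mm
  A2 <- matrix(activity$values, n * n, nz)
  M2 <- matrix(attenuation$values, n * n, nz)
  views <- vector("list", length(angles))
  for (v in seq_along(angles)) {
    rot <- .rotation_operator(n, angles[v])
    act_r <- array(as.matrix(rot %*% A2), c(n, n, nz))
    mu_r <- array(as.matrix(rot %*% M2), c(n, n, nz))
    expect <- .project_frame(act_r, mu_r, model, spec, depth_mm, px,
                             voxel_volume_ml(activity),
                             spec$pixel_size_mm)
    expect <- .add_pedestal(expect, model, spec$collimator, spec$window, px)
    counts <- if (is.null(spec$seed)) expect else
      sample_poisson(expect, spec$seed + v)
    views[[v]] <- list(angle = angles[v], counts = counts,
                       expectation = expect)
  }
  structure(list(views = views, spec = spec, n_inplane = n, nz = nz,
                 voxel_size = activity$voxel_size,
                 origin = activity$origin),
            class = "projection_set")
}
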