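#' Geometric primitive with activity and attenuation class
#'
#' Primitives are the building blocks of digital phantoms. Coordinates are
#' right-handed and in mm with the origin at the phantom centre: x runs
#' right-to-left, y posterior-to-anterior, z inferior-to-superior.
#'
#' @param shape one of "sphere", "cylinder", "box". Cylinders may be
#'   elliptical: give two diameters.
#' @param center numeric length-3, mm.
#' @param dim shape dimensions in mm: sphere `diameter`; cylinder
#'   `c(diameter, height)` or `c(diameter_1, diameter_2, height)`; box
#'   `c(lx, ly, lz)` edge lengths.
#' @param activity activity concentration in kBq/mL (>= 0).
#' @param atten_class one of "water", "contrast_350HU", "air"; mapped to an
#'   effective linear attenuation coefficient per acquisition window by the
#'   detection-model config.
#' @param axis cylinder long axis, "x", "y" or "z" (default "z").
#' @return an object of class `primitive`.
#' @export
primitive <- function(shape = c("sphere", "cylinder", "box"),
                      center = c(0, 0, 0), dim,
                      activity = 0,
                      atten_class = c("water", "contrast_350HU", "air"),
                      axis = "z") {
  shape <- match.arg(shape)
  atten_class <- match.arg(atten_class)
  stopifnot(length(center) == 3, is.finite(center))
  if (any(dim <= 0)) stop("primitive dimensions must be strictly positive")
  if (activity < 0) stop("activity concentration must be >= 0")
  n_dim_ok <- switch(shape, sphere = 1L, cylinder = c(2L, 3L), box = 3L)
  if (!length(dim) %in% n_dim_ok)
    stop("wrong number of dimensions for shape '", shape, "'")
  if (!axis %in% c("x", "y", "z")) stop("axis must be 'x', 'y' or 'z'")
  structure(list(shape = shape, center = as.numeric(center),
                 dim = as.numeric(dim), activity = activity,
                 atten_class = atten_class, axis = axis),
            class = "primitive")
}

#' Analytic volume of a primitive in cm^3
#' @param prim a [primitive].
#' @return volume in cm^3 (mL).
#' @export
primitive_volume <- function(prim) {
  stopifnot(inherits(prim, "primitive"))
  v_mm3 <- switch(prim$shape,
    sphere = 4 / 3 * pi * (prim$dim[1] / 2)^3,
    cylinder = {
      d <- prim$dim
      if (length(d) == 2) pi * (d[1] / 2)^2 * d[2]
      else pi * (d[1] / 2) * (d[2] / 2) * d[3]
    },
    box = prod(prim$dim))
  v_mm3 / 1000
}

#' Assemble a phantom from primitives
#'
#' @param primitives list of [primitive]s; in overlaps, later entries
#'   override earlier ones (deterministic paint order).
#' @param body_outline a [primitive] defining the water-filled envelope;
#'   everything outside it is air.
#' @return an object of class `phantom`.
#' @export
phantom <- function(primitives, body_outline) {
  stopifnot(inherits(body_outline, "primitive"),
            all(vapply(primitives, inherits, logical(1), "primitive")))
  bb <- .prim_bbox(body_outline)
  for (p in primitives) {
    pb <- .prim_bbox(p)
    if (any(pb$lo < bb$lo - 1e-9) || any(pb$hi > bb$hi + 1e-9))
      stop("primitive extends outside the body outline bounding box")
  }
  structure(list(primitives = primitives, body_outline = body_outline),
            class = "phantom")
}

.prim_bbox <- function(p) {
  half <- switch(p$shape,
    sphere = rep(p$dim[1] / 2, 3),
    box = p$dim / 2,
    cylinder = {
      d <- if (length(p$dim) == 2) c(p$dim[1], p$dim[1], p$dim[2]) else p$dim
      r1 <- d[1] / 2; r2 <- d[2] / 2; h <- d[3] / 2
      switch(p$axis, z = c(r1, r2, h), y = c(r1, h, r2), x = c(h, r1, r2))
    })
  list(lo = p$center - half, hi = p$center + half)
}

#' Cylindrical image-quality phantom with an axial hot rod
#'
#' Water cylinder 200 mm diameter x 210 mm height containing a coaxial rod
#' 45 mm diameter x 200 mm height filled at 2.0 kBq/mL; zero background
#' activity.
#'
#' @param rod_activity rod activity concentration, kBq/mL.
#' @return a [phantom].
#' @export
build_cylindrical_phantom <- function(rod_activity = 2.0) {
  body <- primitive("cylinder", c(0, 0, 0), c(200, 210),
                    activity = 0, atten_class = "water")
  rod <- primitive("cylinder", c(0, 0, 0), c(45, 200),
                   activity = rod_activity, atten_class = "water")
  phantom(list(rod), body)
}

#' Modified body phantom: two spheres and an overlapping tube chamber
#'
#' Two identical 28-mm spheres (11.5 cm^3) at 15.0 kBq/mL in iodine-contrast
#' attenuation medium (350 HU), set on one longitudinal (z) axis 80 mm
#' apart, plus a tube-shaped chamber at the same concentration whose
#' anteroposterior projection overlaps sphere 1 but not sphere 2. The tube
#' is a transverse (left-right) cylinder 30 mm diameter x 150 mm length,
#' 60 mm anterior of sphere 1 (centre to centre). The envelope is a
#' water-filled elliptical cylinder 300 (L-R) x 200 (A-P) x 210 mm.
#'
#' @param sphere_activity sphere and tube activity concentration, kBq/mL.
#' @return a [phantom]; primitives named sphere1, sphere2, tube.
#' @export
build_body_phantom <- function(sphere_activity = 15.0) {
  body <- primitive("cylinder", c(0, 0, 0), c(300, 200, 210),
                    activity = 0, atten_class = "water")
  s1 <- primitive("sphere", c(0, -40, 40), 28,
                  activity = sphere_activity, atten_class = "contrast_350HU")
  s2 <- primitive("sphere", c(0, -40, -40), 28,
                  activity = sphere_activity, atten_class = "contrast_350HU")
  tube <- primitive("cylinder", c(0, 20, 40), c(30, 150),
                    activity = sphere_activity, atten_class = "water",
                    axis = "x")
  ph <- phantom(list(s1, s2, tube), body)
  names(ph$primitives) <- c("sphere1", "sphere2", "tube")
  ph
}

#' Voxel grid container
#'
#' A voxel spans the half-open interval
#' `[origin + (i-1)*voxel_size, origin + i*voxel_size)` along each axis
#' (1-based indices); its centre sits at `origin + (i-0.5)*voxel_size`.
#'
#' @param values numeric 3D array (or NULL to allocate zeros from `dims`).
#' @param voxel_size mm per axis (scalar or length-3).
#' @param origin mm coordinates of the low corner of voxel (1,1,1); default
#'   centres the grid on the coordinate origin.
#' @param dims integer length-3, used when `values` is NULL.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values = NULL, voxel_size, origin = NULL, dims = NULL) {
  if (is.null(values)) {
    stopifnot(!is.null(dims), length(dims) == 3, all(dims >= 1))
    values <- array(0, dim = dims)
  }
  stopifnot(length(dim(values)) == 3)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  if (is.null(origin)) origin <- -dim(values) * voxel_size / 2
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' Voxel-centre coordinates of a grid along one axis
#' @param grid a [voxel_grid].
#' @param axis 1, 2 or 3.
#' @return numeric vector of mm coordinates.
#' @export
grid_centers <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 0.5) * grid$voxel_size[axis]
}

#' Voxel volume of a grid in mL
#' @param grid a [voxel_grid].
#' @export
voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

.inside_primitive <- function(p, X, Y, Z) {
  cx <- p$center[1]; cy <- p$center[2]; cz <- p$center[3]
  switch(p$shape,
    sphere = (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2 <= (p$dim[1] / 2)^2,
    box = abs(X - cx) <= p$dim[1] / 2 & abs(Y - cy) <= p$dim[2] / 2 &
      abs(Z - cz) <= p$dim[3] / 2,
    cylinder = {
      d <- if (length(p$dim) == 2) c(p$dim[1], p$dim[1], p$dim[2]) else p$dim
      r1 <- d[1] / 2; r2 <- d[2] / 2; hh <- d[3] / 2
      switch(p$axis,
        z = ((X - cx) / r1)^2 + ((Y - cy) / r2)^2 <= 1 & abs(Z - cz) <= hh,
        y = ((X - cx) / r1)^2 + ((Z - cz) / r2)^2 <= 1 & abs(Y - cy) <= hh,
        x = ((Y - cy) / r1)^2 + ((Z - cz) / r2)^2 <= 1 & abs(X - cx) <= hh)
    })
}

#' Voxelize a phantom onto a grid
#'
#' Voxel-centre membership: a voxel takes a primitive's value iff its
#' centre lies inside the primitive; a voxel inside several primitives
#' takes the last one's value (paint order). Activity grids carry kBq/mL;
#' attenuation grids carry the effective linear attenuation coefficient in
#' 1/cm for the acquisition window, looked up per attenuation class.
#'
#' @param ph a [phantom].
#' @param grid a [voxel_grid] (its values are ignored) covering the phantom
#'   bounding box.
#' @param quantity "activity" or "attenuation".
#' @param mu named vector mapping attenuation classes to 1/cm, e.g.
#'   `c(water = 0.18, contrast_350HU = 0.21, air = 0)`; required for
#'   attenuation grids.
#' @return a [voxel_grid] with filled values.
#' @export
voxelize <- function(ph, grid, quantity = c("activity", "attenuation"),
                     mu = NULL) {
  stopifnot(inherits(ph, "phantom"), inherits(grid, "voxel_grid"))
  quantity <- match.arg(quantity)
  if (quantity == "attenuation" && is.null(mu))
    stop("attenuation voxelization needs a mu lookup (1/cm per class)")
  bb <- .prim_bbox(ph$body_outline)
  glo <- grid$origin
  ghi <- grid$origin + dim(grid$values) * grid$voxel_size
  if (any(bb$lo < glo - 1e-9) || any(bb$hi > ghi + 1e-9))
    stop("grid does not cover the phantom bounding box")
  dims <- dim(grid$values)
  xs <- grid_centers(grid, 1); ys <- grid_centers(grid, 2)
  zs <- grid_centers(grid, 3)
  X <- array(xs, dims)
  Y <- array(rep(ys, each = dims[1]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  vals <- array(0, dims)
  fill_one <- function(p) {
    inside <- .inside_primitive(p, X, Y, Z)
    v <- if (quantity == "activity") p$activity else {
      if (!p$atten_class %in% names(mu))
        stop("no mu entry for class '", p$atten_class, "'")
      unname(mu[p$atten_class])
    }
    vals[inside] <<- v
    invisible(NULL)
  }
  fill_one(ph$body_outline)
  for (p in ph$primitives) fill_one(p)
  voxel_grid(vals, grid$voxel_size, grid$origin)
}

#' Synthetic paired-lesion cohort specification
#'
#' Stand-in for a clinical bone-metastasis cohort: each lesion carries a
#' latent log lesion-to-background contrast shared between two tracers,
#' plus independent per-tracer log-normal noise.
#'
#' @param n_lesions number of lesions (>= 1).
#' @param latent_mean,latent_sd mean and sd of the latent log contrast.
#' @param noise_sd per-tracer multiplicative (log-scale) noise sd.
#' @param seed integer RNG seed.
#' @return an object of class `lesion_cohort_spec`.
#' @export
lesion_cohort_spec <- function(n_lesions = 36, latent_mean = log(10),
                               latent_sd = 0.5, noise_sd = 0.35,
                               seed = 1L) {
  stopifnot(n_lesions >= 1, latent_sd >= 0, noise_sd >= 0)
  structure(list(n_lesions = as.integer(n_lesions),
                 latent_mean = latent_mean, latent_sd = latent_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "lesion_cohort_spec")
}

#' Generate a paired synthetic lesion cohort
#'
#' @param spec a [lesion_cohort_spec].
#' @return data.frame with columns `lesion`, `latent` (log contrast),
#'   `uptake_a`, `uptake_b` (lesion-to-background contrast for the two
#'   tracers). Bit-reproducible under a fixed seed.
#' @export
generate_lesion_cohort <- function(spec) {
  stopifnot(inherits(spec, "lesion_cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  lat <- stats::rnorm(spec$n_lesions, spec$latent_mean, spec$latent_sd)
  ea <- stats::rnorm(spec$n_lesions, 0, spec$noise_sd)
  eb <- stats::rnorm(spec$n_lesions, 0, spec$noise_sd)
  data.frame(lesion = seq_len(spec$n_lesions), latent = lat,
             uptake_a = exp(lat + ea), uptake_b = exp(lat + eb))
}
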