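const_planar <- function(value = 7, n = 20, px = 8.8) {
  structure(list(values = matrix(value, n, n), expectation = NULL,
                 pixel_size = c(px, px), origin = -c(n, n) * px / 2),
            class = "planar_image")
}

test_that("roi_stats matches a brute-force pixel-centre oracle", {
  img <- const_planar()
  rs <- roi_stats(img, roi_spec("circle", c(0, 0), 45))
  expect_equal(rs$mean, 7)
  expect_equal(rs$sd, 0)
  # oracle: exhaustively test pixel centres against the 45-mm circle
  n_in <- 0
  for (i in 1:20) for (j in 1:20) {
    x <- -88 + (i - 0.5) * 8.8; z <- -88 + (j - 0.5) * 8.8
    if (x^2 + z^2 <= 22.5^2) n_in <- n_in + 1
  }
  expect_equal(rs$n, n_in)
  expect_error(roi_stats(img, roi_spec("circle", c(500, 0), 45)), "outside")
})

test_that("hot metrics follow their defining formulas", {
  # image whose rod ROI mean is 300 and whose 8 background ROIs have
  # known means: build directly from region masks
  img <- const_planar(value = 0, n = 40)
  rod <- roi_spec("circle", c(0, 0), 45)
  bvals <- c(90, 95, 100, 105, 110, 100, 95, 105)
  angs <- seq(0, 315, by = 45) * pi / 180
  brois <- lapply(seq_along(angs), function(i)
    roi_spec("circle", 120 * c(cos(angs[i]), sin(angs[i])), 45))
  img$values[ra223spect:::.roi_mask(img, rod)] <- 300
  for (i in seq_along(brois))
    img$values[ra223spect:::.roi_mask(img, brois[[i]])] <- bvals[i]
  m <- hot_metrics(img, rod, brois)
  expect_equal(m$Hr, 300)
  expect_equal(m$BKG, 100)
  expect_equal(m$HBR, 3.0)
  expect_equal(m$SD, sd(bvals))
  expect_equal(m$CNR, 200 / sd(bvals))
  # degenerate: identical background means -> CNR undefined
  img$values[img$values != 300] <- 0
  for (i in seq_along(brois))
    img$values[ra223spect:::.roi_mask(img, brois[[i]])] <- 100
  expect_error(hot_metrics(img, rod, brois), "CNR undefined")
  # Hr == BKG gives CNR 0 (backgrounds 99 and 101 average to the rod mean)
  img$values[ra223spect:::.roi_mask(img, rod)] <- 100
  img$values[ra223spect:::.roi_mask(img, brois[[1]])] <- 99
  img$values[ra223spect:::.roi_mask(img, brois[[2]])] <- 101
  expect_equal(hot_metrics(img, rod, brois)$CNR, 0, tolerance = 1e-12)
})

test_that("isocontour VOI selects the connected super-threshold component", {
  v <- voxel_grid(array(10, c(5, 5, 5)), voxel_size = 10)
  v$values[3, 3, 3] <- 100
  v$values[2, 3, 3] <- v$values[4, 3, 3] <- 60
  v$values[3, 2, 3] <- v$values[3, 4, 3] <- 60
  v$values[3, 3, 2] <- v$values[3, 3, 4] <- 60
  region <- array(TRUE, c(5, 5, 5))
  iso <- isocontour_voi(v, region, 0.6)
  expect_identical(sum(iso$mask), 7L)          # centre + 6 face neighbours
  expect_equal(iso$volume_cm3, 7 * 1)          # 10-mm voxels: 1 mL each
  # frac 1.0 keeps only maximal voxels
  expect_identical(sum(isocontour_voi(v, region, 1.0)$mask), 1L)
  # disconnected hot voxel is not collected
  v$values[1, 1, 1] <- 90
  expect_identical(sum(isocontour_voi(v, region, 0.6)$mask), 7L)
  # flat zero region errors
  z <- voxel_grid(array(0, c(3, 3, 3)), voxel_size = 10)
  expect_error(isocontour_voi(z, array(TRUE, c(3, 3, 3)), 0.6), "flat")
})

test_that("isocontour volume matches an exhaustive thresholding oracle and is monotone", {
  # Gaussian-blurred digital sphere
  g <- voxel_grid(dims = c(21, 21, 21), voxel_size = 4)
  ph <- phantom(list(primitive("sphere", c(0, 0, 0), 28, activity = 1)),
                primitive("box", c(0, 0, 0), c(84, 84, 84)))
  g <- voxelize(ph, g, "activity")
  sm <- butterworth_filter(g, 0.5, 2)   # gentle smoothing
  region <- array(TRUE, dim(sm$values))
  vols <- vapply(c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9), function(f) {
    iso <- isocontour_voi(sm, region, f)
    # oracle: direct count of super-threshold voxels (single component here)
    expect_identical(sum(iso$mask),
                     sum(sm$values >= f * max(sm$values)))
    iso$volume_cm3
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("threshold calibration minimizes summed absolute volume error", {
  tabs <- printed_volume_tables()
  # single-collimator worked example: errors 4.3, 2.5, 5.3, 10.1
  ch_megp <- calibrate_threshold(tabs["MEGP"], 11.5)
  expect_equal(as.numeric(ch_megp), 60)
  expect_equal(unname(attr(ch_megp, "errors")), c(4.3, 2.5, 5.3, 10.1),
               tolerance = 1e-12)
  # both collimators: summed errors 10.7, 3.4, 5.8, 12.6
  ch <- calibrate_threshold(tabs, 11.5)
  expect_equal(as.numeric(ch), 60)
  expect_equal(unname(attr(ch, "errors")), c(10.7, 3.4, 5.8, 12.6),
               tolerance = 1e-12)
  # ties resolve to the lower threshold
  tie <- list(a = c("50" = 10, "60" = 13))   # both err = 1.5 vs 11.5
  expect_equal(as.numeric(calibrate_threshold(tie, 11.5,
                                              candidates = c(50, 60))), 50)
  expect_error(calibrate_threshold(list(), 11.5), "no volume sets")
  expect_error(calibrate_threshold(list(a = c("50" = 1)), 11.5), "missing")
})

test_that("sbr, uptake ratio and lbr follow their defining arithmetic", {
  v <- voxel_grid(array(2, c(20, 20, 10)), voxel_size = 10)
  sph <- roi_spec("sphere", c(0, 0, 0), 40)
  v$values[ra223spect:::.roi_mask(v, sph)] <- 90
  b1 <- roi_spec("sphere", c(-60, -60, 0), 30)
  b2 <- roi_spec("sphere", c(60, -60, 0), 30)
  b3 <- roi_spec("sphere", c(60, 60, 0), 30)
  v$values[ra223spect:::.roi_mask(v, b1)] <- 2
  v$values[ra223spect:::.roi_mask(v, b2)] <- 3
  v$values[ra223spect:::.roi_mask(v, b3)] <- 4
  res <- sbr(v, sph, list(b1, b2, b3))
  expect_equal(res$sbr, 30)
  expect_equal(res$per_background, 90 / c(2, 3, 4))
  expect_equal(uptake_ratio(v, sph, sph), 1)
  # lbr arithmetic: isocontour of the uniform 90-sphere is the sphere
  out <- lbr(v, sph, b1, reference_mean = NULL)
  expect_equal(out$lbr, 45)   # 90 / 2
  # inclusion rule: max only 1.5x the reference -> excluded
  out2 <- lbr(v, sph, b1, reference_mean = 60)
  expect_false(out2$included)
  expect_true(is.na(out2$lbr))
  out3 <- lbr(v, sph, b1, reference_mean = 45)
  expect_true(out3$included)
})

test_that("ratio metrics are invariant to global image scaling", {
  sp <- study_scale_fixture <- local({
    v <- voxel_grid(array(0, c(20, 20, 8)), voxel_size = 10)
    set.seed(9)
    v$values[] <- rexp(length(v$values)) + 0.1
    v
  })
  sph <- roi_spec("sphere", c(0, 0, 0), 40)
  bk <- list(roi_spec("sphere", c(-60, 0, 0), 30),
             roi_spec("sphere", c(60, 0, 0), 30))
  v2 <- sp; v2$values <- sp$values * 37.5
  expect_equal(sbr(v2, sph, bk)$sbr, sbr(sp, sph, bk)$sbr, tolerance = 1e-12)
  expect_equal(uptake_ratio(v2, sph, bk[[1]]), uptake_ratio(sp, sph, bk[[1]]),
               tolerance = 1e-12)
  expect_equal(lbr(v2, sph, bk[[1]])$lbr, lbr(sp, sph, bk[[1]])$lbr,
               tolerance = 1e-12)
  rod <- roi_spec("circle", c(0, 0), 60, slice = 4)
  brois <- lapply(seq(0, 315, 45) * pi / 180, function(a)
    roi_spec("circle", 70 * c(cos(a), sin(a)), 40, slice = 4))
  m1 <- hot_metrics(sp, rod, brois); m2 <- hot_metrics(v2, rod, brois)
  expect_equal(m2$HBR, m1$HBR, tolerance = 1e-12)
  expect_equal(m2$CNR, m1$CNR, tolerance = 1e-12)
})

test_that("linearity fits and the 50-cm3 background sphere radius are exact", {
  res <- linearity(c(1, 2, 4), 3 * c(1, 2, 4))
  expect_equal(res$r, 1)
  expect_equal(res$slope, 3)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_error(linearity(c(1, 2), c(1, 2)), "3")
  expect_error(linearity(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_equal(sphere_radius_mm(50), 22.854, tolerance = 1e-4)
  expect_equal(round(sphere_radius_mm(50) / 10, 2), 2.29)
})
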