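planar_spec <- function(n = 16, seed = NULL, col = "MEGP")
  acquisition_spec("planar", matrix_size = n, pixel_size_mm = 8.8,
                   n_views = 1, angular_step_deg = 180,
                   time_per_view_s = 60, orbit_radius_mm = 150,
                   collimator = col, window = "w84_20", seed = seed)

test_that("planar expectation equals activity x sensitivity x time in the ideal case", {
  m <- ideal_model()
  act <- point_source_grid(total_kbq = 1)     # 1 kBq in one voxel
  mu <- zero_grid_like(act)
  img <- project_planar(act, mu, planar_spec(), m)
  # 1000 Bq x 1e-3 cps/Bq x 60 s = 60 counts in the source pixel column
  expect_equal(sum(img$expectation), 60, tolerance = 1e-10)
  expect_equal(img$expectation[8, 3], 60, tolerance = 1e-10)
  # all-zero activity gives all-zero counts even with noise
  img0 <- project_planar(zero_grid_like(act), mu, planar_spec(seed = 4), m)
  expect_true(all(img0$values == 0))
})

test_that("attenuation follows Beer-Lambert along the ray", {
  m <- ideal_model()
  act <- point_source_grid(total_kbq = 1)
  mu <- zero_grid_like(act)
  # 10 slabs of water (8.8 mm each) between the source and the detector
  mu$values[8, 9:16, ] <- 0.18
  img <- project_planar(act, mu, planar_spec(), m)
  expect_equal(img$expectation[8, 3], 60 * exp(-0.18 * 8 * 0.88),
               tolerance = 1e-10)
})

test_that("collimator blur preserves total counts away from edges", {
  m <- ideal_model(blur = TRUE)
  act <- point_source_grid(n = 32, nz = 11, total_kbq = 2)
  mu <- zero_grid_like(act)
  img <- project_planar(act, mu, planar_spec(n = 32), m)
  expect_equal(sum(img$expectation), 120, tolerance = 1e-6)
  expect_gt(max(img$expectation), 0)
  expect_lt(max(img$expectation), 120)   # spread over several pixels
})

test_that("pedestal adds the configured fraction of detected counts", {
  # wide image so the 120-mm broad kernel is not clipped at the edges
  m <- ideal_model(bf = 0.25, blur = FALSE)
  act <- point_source_grid(n = 64, nz = 49, total_kbq = 1)
  mu <- zero_grid_like(act)
  img <- project_planar(act, mu, planar_spec(n = 64), m)
  # total = primary * (1 + bf/(1-bf)); primary 60
  expect_equal(sum(img$expectation), 60 / (1 - 0.25), tolerance = 1e-6)
})

test_that("spect views of an axially centred source are rotation invariant", {
  # compact smooth blob on the rotation axis (the interpolating rotator
  # conserves totals for smooth fields, not for single-voxel deltas)
  m <- ideal_model()
  g <- voxel_grid(dims = c(27, 27, 5), voxel_size = 8.8)
  ctr <- outer(seq_len(27) - 14, seq_len(27) - 14,
               function(i, j) exp(-(i^2 + j^2) / (2 * 3^2)))
  g$values[, , 3] <- ctr / voxel_volume_ml(g)
  spec <- acquisition_spec("spect", matrix_size = 27, pixel_size_mm = 8.8,
                           n_views = 15, angular_step_deg = 12,
                           time_per_view_s = 60, collimator = "MEGP",
                           window = "w84_20")
  ps <- project_spect(g, zero_grid_like(g), spec, m)
  expect_length(ps$views, 30)
  totals <- vapply(ps$views, function(v) sum(v$expectation), numeric(1))
  expect_lt(diff(range(totals)) / mean(totals), 0.001)
})

test_that("expected counts scale linearly with acquisition time", {
  m <- ideal_model(blur = TRUE)
  g <- point_source_grid(n = 16, nz = 5)
  spec60 <- acquisition_spec("spect", matrix_size = 16, pixel_size_mm = 8.8,
                             n_views = 6, angular_step_deg = 30,
                             time_per_view_s = 60)
  spec120 <- acquisition_spec("spect", matrix_size = 16, pixel_size_mm = 8.8,
                              n_views = 6, angular_step_deg = 30,
                              time_per_view_s = 120)
  p1 <- project_spect(g, zero_grid_like(g), spec60, m)
  p2 <- project_spect(g, zero_grid_like(g), spec120, m)
  t1 <- sum(vapply(p1$views, function(v) sum(v$expectation), numeric(1)))
  t2 <- sum(vapply(p2$views, function(v) sum(v$expectation), numeric(1)))
  expect_equal(t2, 2 * t1, tolerance = 1e-9)
})

test_that("adding activity never decreases any pixel expectation", {
  m <- default_model()
  base <- point_source_grid(n = 16, nz = 5, total_kbq = 1)
  more <- base
  more$values[4, 11, 2] <- more$values[4, 11, 2] + 3 / voxel_volume_ml(base)
  mu <- zero_grid_like(base)
  i1 <- project_planar(base, mu, planar_spec(), m)
  i2 <- project_planar(more, mu, planar_spec(), m)
  expect_true(all(i2$expectation - i1$expectation >= -1e-12))
})

test_that("poisson sampling is reproducible, zero-preserving and unbiased", {
  e <- array(10, c(100, 100))
  a <- sample_poisson(e, 11)
  b <- sample_poisson(e, 11)
  expect_identical(a, b)
  expect_false(identical(a, sample_poisson(e, 12)))
  expect_true(all(sample_poisson(array(0, c(5, 5)), 1) == 0))
  expect_error(sample_poisson(array(-1, c(2, 2)), 1), "non-negative")
  big <- sample_poisson(array(1e4, c(100, 100)), 3)
  expect_lt(abs(mean(big) - 1e4) / 1e4, 0.01)
})

test_that("noisy projection totals agree with expectations within Poisson error", {
  m <- default_model()
  ph <- build_cylindrical_phantom()
  g <- voxel_grid(dims = c(32, 32, 16), voxel_size = 17.6)
  act <- voxelize(ph, g, "activity")
  mu <- voxelize(ph, g, "attenuation", mu = c(water = 0.18,
                                              contrast_350HU = 0.21, air = 0))
  spec <- acquisition_spec("spect", matrix_size = 32, pixel_size_mm = 17.6,
                           n_views = 10, angular_step_deg = 18, seed = 21)
  ps <- project_spect(act, mu, spec, m)
  tot_c <- sum(vapply(ps$views, function(v) sum(v$counts), numeric(1)))
  tot_e <- sum(vapply(ps$views, function(v) sum(v$expectation), numeric(1)))
  expect_lt(abs(tot_c - tot_e), 3 * sqrt(tot_e))
})

test_that("geometry mismatches are rejected", {
  m <- default_model()
  act <- point_source_grid()
  other <- voxel_grid(dims = c(16, 16, 4), voxel_size = 8.8)
  expect_error(project_planar(act, other, planar_spec(), m), "aligned")
  expect_error(acquisition_spec("spect", n_views = 10, angular_step_deg = 10),
               "180")
  spec <- acquisition_spec("spect", matrix_size = 32)
  expect_error(project_spect(act, act, spec, m), "matrix")
})
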