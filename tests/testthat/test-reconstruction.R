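# small self-consistent spect problem: noiseless ideal projections of a
# compact cylinder on a 16 x 16 grid
small_problem <- function(n_views = 8, seed = NULL) {
  m <- ideal_model()
  ph <- phantom(list(primitive("cylinder", c(0, 0, 0), c(50, 30),
                               activity = 4)),
                primitive("cylinder", c(0, 0, 0), c(120, 34),
                          atten_class = "water"))
  g <- voxel_grid(dims = c(16, 16, 4), voxel_size = 8.8)
  act <- voxelize(ph, g, "activity")
  spec <- acquisition_spec("spect", matrix_size = 16, pixel_size_mm = 8.8,
                           n_views = n_views,
                           angular_step_deg = 180 / n_views, seed = seed)
  list(act = act, proj = project_spect(act, zero_grid_like(g), spec, m))
}

test_that("all-zero projections reconstruct to an all-zero volume", {
  sp <- small_problem()
  for (v in seq_along(sp$proj$views)) sp$proj$views[[v]]$counts[] <- 0
  vol <- osem(sp$proj, recon_settings(n_subsets = 2, n_iterations = 3,
                                      filter_cutoff_cpcm = NULL))
  expect_true(all(vol$values == 0))
})

test_that("the OSEM update is homogeneous of degree one in the data", {
  sp <- small_problem()
  s <- recon_settings(n_subsets = 2, n_iterations = 3,
                      filter_cutoff_cpcm = NULL)
  v1 <- osem(sp$proj, s)
  proj3 <- sp$proj
  for (v in seq_along(proj3$views)) proj3$views[[v]]$counts <-
      proj3$views[[v]]$counts * 3
  v3 <- osem(proj3, s)
  expect_equal(v3$values, 3 * v1$values, tolerance = 1e-10)
})

test_that("forward and back projection are exact adjoints", {
  n <- 16; nz <- 3
  rot <- ra223spect:::.rotation_operator(n, 37.5)
  set.seed(1)
  x <- matrix(runif(n * n * nz), n * n, nz)
  y <- matrix(runif(n * nz), n, nz)
  Ax <- ra223spect:::.fwd_view(x, rot, n, nz, 1.7)
  Aty <- ra223spect:::.bwd_view(y, rot, n, nz, 1.7)
  expect_equal(sum(Ax * y), sum(x * Aty), tolerance = 1e-12)
})

test_that("one-subset OSEM matches an independently coded dense MLEM", {
  sp <- small_problem(n_views = 4)
  proj <- sp$proj
  n <- 16; nz <- 1
  # collapse to a single-slice problem
  for (v in seq_along(proj$views)) {
    proj$views[[v]]$counts <- proj$views[[v]]$counts[, 2, drop = FALSE]
    proj$views[[v]]$expectation <- proj$views[[v]]$expectation[, 2, drop = FALSE]
  }
  proj$nz <- 1L
  # dense system matrix from the package's forward operator on basis vectors
  rots <- lapply(proj$views, function(v) ra223spect:::.rotation_operator(n, v$angle))
  nv <- length(proj$views)
  A <- matrix(0, nv * n, n * n)
  for (j in seq_len(n * n)) {
    e <- matrix(0, n * n, 1); e[j] <- 1
    A[, j] <- as.vector(vapply(rots, function(r)
      as.vector(ra223spect:::.fwd_view(e, r, n, 1, 1)), numeric(n)))
  }
  y <- as.vector(vapply(proj$views, function(v) as.vector(v$counts),
                        numeric(n)))
  # textbook dense MLEM, coded independently of the package update
  x <- rep(1, n * n)
  sens <- colSums(A)
  for (it in 1:6) {
    q <- as.vector(A %*% x)
    x <- x * as.vector(t(A) %*% (y / pmax(q, 1e-12))) / pmax(sens, 1e-12)
    x[sens <= 1e-12] <- 0
  }
  vol <- osem(proj, recon_settings(n_subsets = 1, n_iterations = 6,
                                   filter_cutoff_cpcm = NULL))
  expect_equal(as.vector(vol$values), x, tolerance = 1e-8)
})

test_that("MLEM does not decrease the Poisson log-likelihood", {
  sp <- small_problem(n_views = 4, seed = 2)
  proj <- sp$proj
  n <- 16; nz <- 4
  rots <- lapply(proj$views, function(v) ra223spect:::.rotation_operator(n, v$angle))
  loglik <- function(vol) {
    ll <- 0
    for (v in seq_along(proj$views)) {
      lam <- pmax(ra223spect:::.fwd_view(matrix(vol, n * n, nz),
                                         rots[[v]], n, nz, 1), 1e-12)
      y <- proj$views[[v]]$counts
      ll <- ll + sum(y * log(lam) - lam)
    }
    ll
  }
  lls <- vapply(1:5, function(k) {
    vol <- osem(proj, recon_settings(n_subsets = 1, n_iterations = k,
                                     filter_cutoff_cpcm = NULL))
    loglik(vol$values)
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("butterworth filtering preserves constants and the volume mean", {
  g <- voxel_grid(array(7, c(16, 16, 8)), voxel_size = 8.8)
  f <- butterworth_filter(g, 0.20, 10)
  expect_equal(f$values, g$values, tolerance = 1e-10)
  set.seed(4)
  g$values[] <- runif(length(g$values))
  f <- butterworth_filter(g, 0.20, 10)
  expect_equal(mean(f$values), mean(g$values), tolerance = 1e-12)
  expect_lt(stats::sd(f$values), stats::sd(g$values))  # low-pass
})

test_that("butterworth closed-form gains hold at DC, cutoff and twice cutoff", {
  expect_equal(butterworth_gain(0, 0.20, 10), 1)
  expect_equal(butterworth_gain(0.20, 0.20, 10), 1 / sqrt(2))
  expect_equal(butterworth_gain(0.40, 0.20, 10), 1 / sqrt(1 + 2^20))
  expect_equal(butterworth_gain(0.40, 0.20, 10), 9.765e-4, tolerance = 1e-3)
})

test_that("butterworth acts on physical frequencies: a pure mode is scaled by its gain", {
  n <- 32; vox <- 8.8
  k <- 4   # cycles across the grid along x
  f_cpcm <- k / (n * vox) * 10
  xs <- seq_len(n) - 1
  mode <- array(cos(2 * pi * k * xs / n), c(n, n, 4))
  g <- voxel_grid(mode, voxel_size = vox)
  out <- butterworth_filter(g, 0.20, 10)
  expect_equal(out$values,
               mode * butterworth_gain(f_cpcm, 0.20, 10),
               tolerance = 1e-10)
})
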