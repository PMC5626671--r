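# Shared fixtures. Heavy end-to-end runs are memoised so several test
# files (and the acceptance checks) can share one simulation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

default_model <- function() memo("model", ra223_model())

# detection model stripped of blur, pedestal and (optionally) attenuation:
# lets projection tests check closed-form expectations
ideal_model <- function(bf = 0, blur = FALSE) {
  m <- ra223_model()
  for (cn in names(m$collimators)) {
    if (!blur)
      m$collimators[[cn]]$resolution <- list(fwhm0_mm = 0, slope_mm_per_mm = 0)
    for (w in names(m$collimators[[cn]]$background_fraction))
      m$collimators[[cn]]$background_fraction[[w]] <- bf
  }
  m
}

# single hot voxel of known total activity on a small grid
point_source_grid <- function(n = 16, nz = 5, voxel_mm = 8.8,
                              total_kbq = 1) {
  g <- voxel_grid(dims = c(n, n, nz), voxel_size = voxel_mm)
  conc <- total_kbq / voxel_volume_ml(g)   # kBq/mL so the voxel holds total_kbq
  g$values[n / 2, n / 2, ceiling(nz / 2)] <- conc
  g
}

zero_grid_like <- function(g) voxel_grid(dims = dim(g$values),
                                         voxel_size = g$voxel_size,
                                         origin = g$origin)

# full body-phantom study (shared by several acceptance checks)
study_b_fixture <- function() memo("study_b", run_study_b(seed = 101))

study_a_fixture <- function() memo("study_a", run_study_a(seed = 202))

# printed sphere-2 isocontour volume tables (cm^3) at candidate thresholds,
# as measured on the physical phantom with each collimator
printed_volume_tables <- function() {
  list(MEGP = c("50" = 15.8, "60" = 9.0, "70" = 6.2, "80" = 1.4),
       HEGP = c("50" = 17.9, "60" = 12.4, "70" = 11.0, "80" = 9.0))
}
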