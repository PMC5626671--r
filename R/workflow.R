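# End-to-end study orchestration: the cylinder image-quality study
# (study A), the body-phantom planar-vs-SPECT study (study B), and the
# synthetic clinical-correlation study. Each run_* returns a report list
# whose tables are fully reproducible from the embedded config and seed.

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[ra223spect] %s", sprintf(fmt, ...)))
}

#' Default SPECT voxel grid for the 64 x 64 acquisition
#' @param nz number of axial slices.
#' @param n in-plane matrix size.
#' @param voxel_mm isotropic voxel size, mm.
#' @return an empty [voxel_grid] centred on the origin.
#' @export
spect_grid <- function(nz = 24, n = 64, voxel_mm = 8.8) {
  voxel_grid(dims = c(n, n, nz), voxel_size = voxel_mm)
}

# simulate + reconstruct one SPECT condition of a phantom
.spect_recon <- function(ph, grid, model, collimator, window, seed,
                         time_s = 60, settings = recon_settings(),
                         n_views = 30) {
  act <- voxelize(ph, grid, "activity")
  mu <- voxelize(ph, grid, "attenuation", mu = .mu_table(model, window))
  spec <- acquisition_spec("spect", matrix_size = dim(grid$values)[1],
                           pixel_size_mm = grid$voxel_size[1],
                           n_views = n_views,
                           angular_step_deg = 180 / n_views,
                           time_per_view_s = time_s,
                           collimator = collimator, window = window,
                           seed = seed)
  proj <- project_spect(act, mu, spec, model)
  osem(proj, settings)
}

#' Run the cylinder image-quality study
#'
#' Simulates the hot-rod cylinder phantom for every collimator x window
#' condition, reconstructs with OSEM + Butterworth, measures Hr, BKG, SD,
#' HBR and CNR on `n_replicates` transaxial slices (45-mm rod ROI, eight
#' 45-mm background ROIs at 70 mm radius), and runs the statistical
#' battery: Wilcoxon signed-rank for the 84 keV +-20% vs +-10% window
#' comparison, Friedman across the three energy windows with Steel-Dwass
#' pairs, and Wilcoxon for the HEGP-vs-MEGP background comparison per
#' window.
#'
#' @param seed master seed.
#' @param n_replicates number of analysis slices.
#' @param collimators,windows condition grids.
#' @param model a [ra223_model()].
#' @param settings a [recon_settings].
#' @param verbose log stage progress.
#' @return report list: `metrics` (one row per condition x slice), `tests`,
#'   `config`.
#' @export
run_study_a <- function(seed = 1L, n_replicates = 10,
                        collimators = c("MEGP", "HEGP"),
                        windows = c("w84_20", "w84_10", "w154_10", "w269_05"),
                        model = ra223_model(),
                        settings = recon_settings(),
                        verbose = FALSE) {
  stopifnot(n_replicates >= 1)
  for (w in windows) .model_window(model, w)
  ph <- build_cylindrical_phantom()
  grid <- spect_grid()
  # replicate slices: evenly spaced within the rod extent (|z| <= 80 mm)
  zs <- grid_centers(grid, 3)
  ok <- which(abs(zs) <= 80)
  slices <- ok[unique(round(seq(1, length(ok), length.out = n_replicates)))]
  rod_roi <- function(k) roi_spec("circle", c(0, 0), 45, slice = k)
  bkg_rois <- function(k) lapply(seq(0, 315, by = 45) * pi / 180, function(a)
    roi_spec("circle", 70 * c(cos(a), sin(a)), 45, slice = k))
  metrics <- NULL
  for (col in collimators) for (w in windows) {
    .log_stage(verbose, "study A: %s / %s", col, w)
    # common random numbers across windows of one collimator: the window
    # comparison is then paired, as successive scans of one phantom are
    cond_seed <- seed + 1000 * match(col, collimators)
    vol <- .spect_recon(ph, grid, model, col, w, cond_seed,
                        settings = settings)
    for (k in slices) {
      m <- hot_metrics(vol, rod_roi(k), bkg_rois(k))
      metrics <- rbind(metrics, data.frame(
        collimator = col, window = w, slice = k,
        Hr = m$Hr, BKG = m$BKG, SD = m$SD, HBR = m$HBR, CNR = m$CNR))
    }
  }
  tests <- .study_a_tests(metrics, collimators, windows)
  list(metrics = metrics, tests = tests,
       config = list(seed = seed, n_replicates = n_replicates,
                     collimators = collimators, windows = windows,
                     slices = slices, settings = unclass(settings)))
}

.study_a_tests <- function(metrics, collimators, windows) {
  tests <- NULL
  get <- function(col, w, what) {
    m <- metrics[metrics$collimator == col & metrics$window == w, ]
    m[[what]][order(m$slice)]
  }
  add <- function(comparison, collimator, metric, res) {
    tests <<- rbind(tests, data.frame(
      comparison = comparison, collimator = collimator, metric = metric,
      method = res$method, statistic = res$statistic,
      p_value = res$p_value))
  }
  for (col in collimators) {
    if (all(c("w84_20", "w84_10") %in% windows)) {
      for (what in c("Hr", "BKG", "HBR", "CNR"))
        add("w84_20 vs w84_10", col, what,
            wilcoxon_signed_rank(get(col, "w84_20", what),
                                 get(col, "w84_10", what)))
    }
    three <- intersect(c("w84_20", "w154_10", "w269_05"), windows)
    if (length(three) == 3) {
      for (what in c("Hr", "BKG", "HBR", "CNR")) {
        mat <- sapply(three, function(w) get(col, w, what))
        fr <- friedman_rank_test(mat)
        add("across windows", col, what, fr)
        if (fr$p_value < 0.05) {
          sd_res <- steel_dwass(lapply(three, function(w) get(col, w, what)))
          for (q in seq_len(nrow(sd_res)))
            add(sprintf("steel_dwass %s vs %s", three[sd_res$group1[q]],
                        three[sd_res$group2[q]]), col, what,
                .stat_result("steel_dwass", sd_res$statistic[q],
                             sd_res$p_adjusted[q], FALSE, NA_integer_))
        }
      }
    }
  }
  if (all(c("MEGP", "HEGP") %in% collimators)) {
    for (w in windows)
      add("HEGP vs MEGP", w, "BKG",
          wilcoxon_signed_rank(get("HEGP", w, "BKG"), get("MEGP", w, "BKG")))
  }
  tests
}

# background region layouts for the body phantom (avoiding the spheres and
# the tube-chamber projection); frozen config of the study
.planar_bkg_centers <- function() {
  rbind(cbind(c(-85, 85, -85, 85), c(-78, -78, 78, 78)),
        cbind(c(-115, 115), c(0, 0)),
        cbind(c(-45, 45), c(-78, -78)))
}

.spect_bkg_centers <- function() {
  as.matrix(expand.grid(x = c(-85, 85), y = c(-45, 45), z = c(-80, 80)))
}

#' Run the body-phantom planar-vs-SPECT study
#'
#' For each collimator: a 30-min anteroposterior planar static
#' (128 x 128, 4.4 mm) and a SPECT acquisition of the two-sphere + tube
#' phantom, reconstructed with OSEM + Butterworth. Computes the
#' isocontour-VOI threshold-calibration table for sphere 2 (50-80% of
#' maximum), the sphere1/sphere2 uptake ratio (28-mm planar ROIs vs 60%
#' SPECT VOIs), the sphere-2 SBR against eight 48-mm background
#' ROIs/VOIs, the count-linearity fit across activity concentrations, and
#' the Wilcoxon comparisons (planar vs SPECT; MEGP vs HEGP).
#'
#' @param seed master seed.
#' @param collimators collimators to compare.
#' @param concentrations kBq/mL levels for the linearity scan (the highest
#'   doubles as the main study acquisition).
#' @param model a [ra223_model()].
#' @param settings a [recon_settings].
#' @param window energy window (the clinically selected wide window).
#' @param verbose log stage progress.
#' @return report list with `ratios`, `threshold_volumes`,
#'   `chosen_threshold`, `linearity`, `tests`, `config`.
#' @export
run_study_b <- function(seed = 1L, collimators = c("MEGP", "HEGP"),
                        concentrations = c(3.75, 7.5, 15.0),
                        model = ra223_model(),
                        settings = recon_settings(),
                        window = "w84_20", verbose = FALSE) {
  main_conc <- max(concentrations)
  grid <- spect_grid()
  planar_grid <- voxel_grid(dims = c(128, 46, 48), voxel_size = 4.4)
  s1_center <- c(0, -40, 40); s2_center <- c(0, -40, -40)
  ratios <- NULL; thr_vols <- list(); lin <- list(); sbr_pairs <- list()
  cond_id <- 0
  for (col in collimators) {
    cond_id <- cond_id + 1
    ph <- build_body_phantom(main_conc)
    .log_stage(verbose, "study B planar: %s", col)
    act_p <- voxelize(ph, planar_grid, "activity")
    mu_p <- voxelize(ph, planar_grid, "attenuation",
                     mu = .mu_table(model, window))
    pspec <- acquisition_spec("planar", matrix_size = 128,
                              pixel_size_mm = 4.4, n_views = 1,
                              angular_step_deg = 180,
                              time_per_view_s = 1800,
                              orbit_radius_mm = 150,
                              collimator = col, window = window,
                              seed = seed + 10000 * cond_id)
    planar <- project_planar(act_p, mu_p, pspec, model)
    up_planar <- uptake_ratio(planar,
                              roi_spec("circle", c(0, 40), 28),
                              roi_spec("circle", c(0, -40), 28))
    pb <- .planar_bkg_centers()
    planar_bkgs <- lapply(seq_len(nrow(pb)), function(i)
      roi_spec("circle", pb[i, ], 48))
    sbr_planar <- sbr(planar, roi_spec("circle", c(0, -40), 28), planar_bkgs)

    .log_stage(verbose, "study B SPECT: %s", col)
    vol <- .spect_recon(ph, grid, model, col, window,
                        seed + 10000 * cond_id + 1, settings = settings)
    search2 <- roi_spec("sphere", s2_center, 56)
    vols <- vapply(c(50, 60, 70, 80) / 100, function(f)
      isocontour_voi(vol, search2, f)$volume_cm3, numeric(1))
    names(vols) <- c("50", "60", "70", "80")
    thr_vols[[col]] <- vols
    voi1 <- isocontour_voi(vol, roi_spec("sphere", s1_center, 56), 0.6)
    voi2 <- isocontour_voi(vol, search2, 0.6)
    up_spect <- uptake_ratio(vol, voi1$mask, voi2$mask)
    sb <- .spect_bkg_centers()
    spect_bkgs <- lapply(seq_len(nrow(sb)), function(i)
      roi_spec("sphere", as.numeric(sb[i, ]), 48))
    sbr_spect <- sbr(vol, voi2$mask, spect_bkgs)
    ratios <- rbind(ratios, data.frame(
      collimator = col,
      uptake_ratio_planar = up_planar, uptake_ratio_spect = up_spect,
      sbr_planar = sbr_planar$sbr, sbr_spect = sbr_spect$sbr))
    sbr_pairs[[col]] <- list(planar = sbr_planar$per_background,
                             spect = sbr_spect$per_background)

    # linearity: lower concentrations re-simulated, highest reuses `vol`
    means <- numeric(length(concentrations))
    for (ci in seq_along(concentrations)) {
      cc <- concentrations[ci]
      v <- if (cc == main_conc) vol else
        .spect_recon(build_body_phantom(cc), grid, model, col, window,
                     seed + 10000 * cond_id + 1 + ci, settings = settings)
      means[ci] <- mean(v$values[isocontour_voi(v, search2, 0.6)$mask])
    }
    lin[[col]] <- linearity(concentrations, means)
  }
  chosen <- calibrate_threshold(thr_vols, 11.5)
  tests <- NULL
  for (col in collimators) {
    res <- wilcoxon_signed_rank(sbr_pairs[[col]]$spect,
                                sbr_pairs[[col]]$planar)
    tests <- rbind(tests, data.frame(
      comparison = "SBR spect vs planar", collimator = col,
      method = res$method, statistic = res$statistic,
      p_value = res$p_value))
  }
  if (all(c("MEGP", "HEGP") %in% collimators)) {
    for (mode in c("planar", "spect")) {
      res <- wilcoxon_signed_rank(sbr_pairs[["HEGP"]][[mode]],
                                  sbr_pairs[["MEGP"]][[mode]])
      tests <- rbind(tests, data.frame(
        comparison = sprintf("SBR HEGP vs MEGP (%s)", mode),
        collimator = NA, method = res$method, statistic = res$statistic,
        p_value = res$p_value))
    }
  }
  list(ratios = ratios, threshold_volumes = thr_vols,
       chosen_threshold = as.numeric(chosen),
       threshold_errors = attr(chosen, "errors"),
       linearity = lin, tests = tests,
       config = list(seed = seed, collimators = collimators,
                     concentrations = concentrations, window = window,
                     settings = unclass(settings)))
}

#' Build the single-lesion phantom used by the synthetic clinical study
#'
#' A water-filled elliptical-cylinder torso section with uniform soft-
#' tissue background activity (the designated "liver" background
#' compartment), a normal-spine rod, and one spherical lesion inside the
#' spine whose lesion-to-background contrast is supplied per lesion.
#'
#' Ra-223 is bone-seeking: soft tissue (and liver) carries on the order
#' of one percent of lesion concentration, so background-VOI counts in
#' the reconstruction are dominated by the septal-penetration/scatter
#' pedestal generated by the patient's overall activity burden — normal
#' skeleton plus the excreted bowel activity that most patients show —
#' rather than by true background uptake. In this regime the collimator's
#' background fraction, not background activity, sets the lesion-to-
#' background ratio. Lesion concentration is
#' `lesion_contrast * lesion_unit_kbq_ml`.
#'
#' @param lesion_contrast lesion uptake as a multiple of the unit scale.
#' @param lesion_unit_kbq_ml concentration corresponding to contrast 1.
#' @param spine_kbq_ml normal-spine concentration.
#' @param bowel_kbq_ml excreted-activity concentration in the bowel-like
#'   transverse chamber (often exceeds metastatic uptake).
#' @param background_kbq_ml soft-tissue background concentration.
#' @return a [phantom].
#' @export
build_lesion_phantom <- function(lesion_contrast,
                                 lesion_unit_kbq_ml = 0.2,
                                 spine_kbq_ml = 0.5,
                                 bowel_kbq_ml = 2.0,
                                 background_kbq_ml = 0.02) {
  body <- primitive("cylinder", c(0, 0, 0), c(260, 170, 130),
                    activity = background_kbq_ml, atten_class = "water")
  spine <- primitive("cylinder", c(0, -50, 0), c(30, 100),
                     activity = spine_kbq_ml, atten_class = "water")
  bowel <- primitive("cylinder", c(0, 30, 0), c(40, 180),
                     activity = bowel_kbq_ml, atten_class = "water",
                     axis = "x")
  lesion <- primitive("sphere", c(0, -50, 25), 28,
                      activity = lesion_contrast * lesion_unit_kbq_ml,
                      atten_class = "water")
  phantom(list(spine, bowel, lesion), body)
}

#' Run the synthetic clinical-correlation study
#'
#' Generates a paired lesion cohort, images every lesion with the Ra-223
#' model under both collimators and with a high-count reference-tracer
#' model, computes LBRme / LBRhe / LBRtc using the 60% isocontour lesion
#' VOI and a 50 cm^3 spherical background VOI, applies the two-times-
#' normal-spine inclusion rule, and reports the pairwise correlations and
#' the paired t comparison of LBRme vs LBRhe.
#'
#' @param cohort a [lesion_cohort_spec].
#' @param seed master imaging seed (cohort seed lives in the spec).
#' @param model a [ra223_model()].
#' @param settings a [recon_settings].
#' @param verbose log stage progress.
#' @return report list with `lesions` (per-lesion table), `correlations`,
#'   `paired_t`, `config`.
#' @export
run_clinical_sim <- function(cohort = lesion_cohort_spec(), seed = 1L,
                             model = ra223_model(),
                             settings = recon_settings(),
                             verbose = FALSE) {
  coh <- generate_lesion_cohort(cohort)
  grid <- spect_grid(nz = 16, n = 32)
  lesion_center <- c(0, -50, 25)
  search <- roi_spec("sphere", lesion_center, 50)
  bkg_voi <- roi_spec("sphere", c(75, -25, -25), 2 * sphere_radius_mm(50))
  ref_voi <- roi_spec("sphere", c(0, -50, -30), 30)
  conds <- list(me = c("MEGP", "w84_20"), he = c("HEGP", "w84_20"),
                tc = c("REF", "ref"))
  rows <- NULL
  for (i in seq_len(nrow(coh))) {
    .log_stage(verbose, "clinical sim: lesion %d / %d", i, nrow(coh))
    out <- list()
    for (cn in names(conds)) {
      uptake <- if (cn == "tc") coh$uptake_b[i] else coh$uptake_a[i]
      ph <- build_lesion_phantom(uptake)
      # the two Ra-223 collimators image the same lesion back to back:
      # share the random-number stream so their comparison is paired
      cond_seed <- seed + 100 * i + if (cn == "tc") 2 else 1
      vol <- .spect_recon(ph, grid, model, conds[[cn]][1], conds[[cn]][2],
                          cond_seed, settings = settings)
      ref_mean <- mean(.region_values(vol, ref_voi))
      out[[cn]] <- lbr(vol, search, bkg_voi, reference_mean = ref_mean)
    }
    rows <- rbind(rows, data.frame(
      lesion = i, uptake_ra = coh$uptake_a[i], uptake_ref = coh$uptake_b[i],
      lbr_me = out$me$lbr, lbr_he = out$he$lbr, lbr_tc = out$tc$lbr,
      included_me = out$me$included, included_he = out$he$included))
  }
  keep <- rows$included_me & rows$included_he & !is.na(rows$lbr_tc)
  kept <- rows[keep, ]
  correlations <- if (nrow(kept) >= 3) list(
    me_vs_tc = pearson_regression(kept$lbr_tc, kept$lbr_me),
    he_vs_tc = pearson_regression(kept$lbr_tc, kept$lbr_he)) else NULL
  pt <- if (nrow(kept) >= 3) paired_t(kept$lbr_he, kept$lbr_me) else NULL
  list(lesions = rows, kept = which(keep), correlations = correlations,
       paired_t = pt,
       frac_he_higher = mean(kept$lbr_he > kept$lbr_me),
       config = list(cohort = unclass(cohort), seed = seed,
                     settings = unclass(settings)))
}
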