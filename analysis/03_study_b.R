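#!/usr/bin/env Rscript
# Body-phantom study: planar vs SPECT separation of overlapping activity,
# isocontour-threshold calibration for the 28-mm sphere, sphere-to-
# background ratios, and count linearity across concentrations.

suppressPackageStartupMessages(library(ra223spect))
dir.create("results", showWarnings = FALSE)

report <- run_study_b(seed = 101, verbose = TRUE)
write.csv(report$ratios, "results/study_b_ratios.csv", row.names = FALSE)
write.csv(report$tests, "results/study_b_tests.csv", row.names = FALSE)

thr <- do.call(rbind, lapply(names(report$threshold_volumes), function(col)
  data.frame(collimator = col,
             threshold_pct = as.numeric(names(report$threshold_volumes[[col]])),
             volume_cm3 = unname(report$threshold_volumes[[col]]))))
write.csv(thr, "results/study_b_threshold_volumes.csv", row.names = FALSE)

lin <- do.call(rbind, lapply(names(report$linearity), function(col) {
  l <- report$linearity[[col]]
  data.frame(collimator = col, concentration_kbq_ml = l$concentrations,
             mean_counts = l$counts, r = l$r, slope = l$slope)
}))
write.csv(lin, "results/study_b_linearity.csv", row.names = FALSE)

cat("\nUptake ratios and SBR:\n")
print(report$ratios, digits = 4)
cat("\nFindings:\n")
for (i in seq_len(nrow(report$ratios))) {
  r <- report$ratios[i, ]
  cat(sprintf(
    " - %s: planar sphere1/sphere2 = %.2f (tube overlay inflates sphere 1),\n   SPECT ratio = %.2f (spheres separated); SBR %.1f (planar) -> %.1f (SPECT), x%.1f.\n",
    r$collimator, r$uptake_ratio_planar, r$uptake_ratio_spect,
    r$sbr_planar, r$sbr_spect, r$sbr_spect / r$sbr_planar))
}
cat(sprintf(" - Simulated threshold-volume table selects %.0f%%; the physical-phantom tables select 60%% (see vignette on partial volume at this voxel scale).\n",
            report$chosen_threshold))
for (col in names(report$linearity))
  cat(sprintf(" - %s linearity over %s kBq/mL: r = %.5f.\n", col,
              paste(report$linearity[[col]]$concentrations, collapse = "/"),
              report$linearity[[col]]$r))
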