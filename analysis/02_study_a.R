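#!/usr/bin/env Rscript
# Cylinder image-quality study: compare energy windows (84 keV +-20% vs
# +-10%, then 84/154/269 keV) and collimators (MEGP vs HEGP) on Hr, BKG,
# HBR and CNR measured over 10 transaxial slices, with the Wilcoxon /
# Friedman / Steel-Dwass battery.

suppressPackageStartupMessages(library(ra223spect))
dir.create("results", showWarnings = FALSE)

report <- run_study_a(seed = 202, verbose = TRUE)
write.csv(report$metrics, "results/study_a_metrics.csv", row.names = FALSE)
write.csv(report$tests, "results/study_a_tests.csv", row.names = FALSE)

med <- aggregate(cbind(Hr, BKG, HBR, CNR) ~ collimator + window,
                 report$metrics, median)
write.csv(med, "results/study_a_medians.csv", row.names = FALSE)
cat("\nCondition medians (10 slices each):\n")
print(med, digits = 4)

pick <- function(col, w, what) med[[what]][med$collimator == col &
                                           med$window == w]
cat("\nFindings:\n")
for (col in c("MEGP", "HEGP")) {
  cat(sprintf(
    " - %s: widening 84 keV +-10%% -> +-20%% multiplies Hr by %.2f and CNR by %.2f;\n   HBR changes by only %.1f%% (window width moves counts, not contrast).\n",
    col, pick(col, "w84_20", "Hr") / pick(col, "w84_10", "Hr"),
    pick(col, "w84_20", "CNR") / pick(col, "w84_10", "CNR"),
    100 * abs(pick(col, "w84_20", "HBR") / pick(col, "w84_10", "HBR") - 1)))
}
for (w in c("w84_20", "w84_10", "w154_10", "w269_05"))
  cat(sprintf(" - %s: background %.4f (HEGP) vs %.4f (MEGP) — HEGP pedestal lower.\n",
              w, pick("HEGP", w, "BKG"), pick("MEGP", w, "BKG")))
cat(sprintf(" - HBR at 84 keV +-20%%: %.1f (HEGP) vs %.1f (MEGP).\n",
            pick("HEGP", "w84_20", "HBR"), pick("MEGP", "w84_20", "HBR")))

sig <- report$tests[report$tests$p_value < 0.05, ]
cat(sprintf("\n%d of %d statistical comparisons significant at p < 0.05 (see results/study_a_tests.csv)\n",
            nrow(sig), nrow(report$tests)))
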