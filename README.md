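# ra223spect

Desk-scale simulation and semi-quantitative analysis of Ra-223 SPECT
phantom studies.

Ra-223 dichloride is an alpha-emitting, bone-seeking therapeutic for
castration-resistant prostate cancer with bone metastases. Imaging its
uptake is hard: injected activities are a few MBq, the photon spectrum is
broad, and a large share of detected counts are septal-penetration and
scatter background. Planar imaging additionally superimposes bowel
activity on the lumbar spine. This package implements, as a tested R
pipeline, the phantom analyses that justify acquiring Ra-223 with SPECT,
a high-energy general-purpose (HEGP) collimator and a wide 84 keV ± 20%
energy window:

* digital phantoms (hot-rod cylinder; two-sphere body phantom with an
  overlapping tube chamber; single-lesion torso sections) voxelized from
  geometric primitives;
* a collimator/energy-window detection model (window sensitivities and
  background pedestal fractions parameterized from measured spectra)
  with depth-dependent resolution;
* planar and dual-head SPECT forward projection with Beer–Lambert
  attenuation, distance-dependent blur, pedestal background and Poisson
  noise;
* OSEM reconstruction (5 subsets × 10 iterations, no attenuation or
  scatter correction, as in the Ra-223 protocol) with 3D Butterworth
  post-filtering, gain `1/sqrt(1 + (f/fc)^(2n))` at cutoff
  0.20 cycles/cm, order 10;
* the semi-quantitative metrics `Hr`, `BKG`, `SD`, `HBR = Hr/BKG`,
  `CNR = (Hr − BKG)/SD`, sphere-to-background ratio (SBR),
  lesion-to-background ratio (LBR), isocontour-VOI segmentation with
  volume-matching threshold calibration, and count-linearity fits;
* the matching nonparametric battery: exact Wilcoxon signed-rank
  (2^m enumeration up to m = 15), Friedman, Steel–Dwass all-pairs
  (studentized-range or permutation p-values), paired t, and Pearson
  regression.

## Worked example

Simulate the hot-rod cylinder with the HEGP collimator at 84 keV ± 20%,
reconstruct, and measure image quality on one transaxial slice:

```r
library(ra223spect)

model <- ra223_model()
ph   <- build_cylindrical_phantom()        # water cylinder + 2.0 kBq/mL rod
grid <- spect_grid()                       # 64 x 64 x 24 at 8.8 mm
act  <- voxelize(ph, grid, "activity")
mu   <- voxelize(ph, grid, "attenuation",
                 mu = c(water = 0.18, contrast_350HU = 0.21, air = 0))

spec <- acquisition_spec("spect", collimator = "HEGP", window = "w84_20",
                         seed = 1)         # 30 frames/head, 6 deg, 60 s
proj <- project_spect(act, mu, spec, model)
vol  <- osem(proj, recon_settings())       # OSEM 5x10 + Butterworth 0.20/10

hot_metrics(vol,
            roi_spec("circle", c(0, 0), 45, slice = 12),
            lapply(seq(0, 315, 45) * pi / 180, function(a)
              roi_spec("circle", 70 * c(cos(a), sin(a)), 45, slice = 12)))
#> $Hr  11.2      mean counts in the 45-mm rod ROI
#> $BKG  0.175    mean of the eight 45-mm background ROI means
#> $SD   0.016    their standard deviation
#> $HBR 63.8      rod-to-background contrast
#> $CNR  687      contrast-to-noise ratio
```

The rod stands out at ~64× background; repeating with `window =
"w84_10"` halves `Hr` and `BKG` (half the primaries enter the narrow
window) while `HBR` is essentially unchanged and `CNR` drops by roughly
1/√2 — the count-statistics argument for the wide window.

## The three studies

The numbered drivers under `analysis/` run the full studies and write
their tables under `results/`:

```sh
Rscript analysis/01_phantoms.R      # phantom geometry summaries
Rscript analysis/02_study_a.R      # window/collimator image quality + stats
Rscript analysis/03_study_b.R      # planar vs SPECT, thresholds, linearity
Rscript analysis/04_clinical_sim.R # synthetic paired lesion cohort, LBRs
```

Typical findings at the default study conditions: widening the 84-keV
window doubles rod counts with HBR changed by under 2% and CNR up by
~1.4×; the HEGP collimator shows lower background than MEGP at every
window; the planar sphere-1/sphere-2 ratio is inflated by the
overlapping tube chamber while SPECT returns ≈ 1.05; SPECT SBR exceeds
planar SBR several-fold; reconstructed counts are linear in activity
concentration (r > 0.999); and lesion-to-background ratios correlate
across tracers at r ≈ 0.7 with LBR(HEGP) > LBR(MEGP) lesion-wise.

## Package layout

```
R/                 phantoms, detection model, projector, OSEM/Butterworth,
                   quantification, nonparametric statistics, workflows, IO
inst/extdata/      ra223_model.yaml — the versioned default detection model
analysis/          numbered study drivers (write results/ tables)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (model, assumptions, design choices)
```
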