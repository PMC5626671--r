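# Default Ra-223 detection model: energy windows, collimator-dependent
# window sensitivities and background (septal-penetration + scatter
# pedestal) fractions, collimator resolution, and effective attenuation
# coefficients per window.
#
# Sensitivity scale: only ratios between conditions matter to the
# ratio-type metrics; the absolute anchor (MEGP, 84 keV +-20%) is set to
# 1.0e-3 cps per Bq at the 100 mm reference distance so that 60-s frames
# give desk-scale count statistics. All other sensitivities derive from
# the measured relative-sensitivity and relative-peak-height table:
#   HEGP/MEGP at 84 keV  = 99.5 %
#   HEGP/MEGP at 154 keV = 70.2 %
#   HEGP/MEGP at 269 keV = 69.8 %
#   HEGP peak height relative to 84 keV: 154 keV 29.3 %, 269 keV 18.9 %
# The +-20% window collects twice the primaries of the +-10% window (the
# 75-keV lead K-alpha line enters the wide window); the factor 2.0 is a
# configured surrogate, not a measured value.
version: 1
windows:
  w84_20:  {center: 84.0,  half_width_fraction: 0.20}
  w84_10:  {center: 84.0,  half_width_fraction: 0.10}
  w154_10: {center: 154.0, half_width_fraction: 0.10}
  w269_05: {center: 269.0, half_width_fraction: 0.05}
  ref:     {center: 141.0, half_width_fraction: 0.10}
# effective linear attenuation coefficient (1/cm) per attenuation class,
# single effective value per acquisition window
attenuation_mu_cm:
  w84_20:  {water: 0.180, contrast_350HU: 0.210, air: 0.0}
  w84_10:  {water: 0.180, contrast_350HU: 0.210, air: 0.0}
  w154_10: {water: 0.150, contrast_350HU: 0.175, air: 0.0}
  w269_05: {water: 0.125, contrast_350HU: 0.145, air: 0.0}
  ref:     {water: 0.150, contrast_350HU: 0.175, air: 0.0}
# pedestal spatial model: primaries convolved with a broad Gaussian plus a
# flat floor, mixed by the weights below; total pedestal counts equal
# primaries * background_fraction / (1 - background_fraction)
pedestal:
  broad_fwhm_mm: 120.0
  broad_weight: 0.7
  flat_weight: 0.3
collimators:
  MEGP:
    hole_diameter_mm: 3.0
    hole_length_mm: 58.0
    septal_thickness_mm: 1.1
    resolution: {fwhm0_mm: 4.0, slope_mm_per_mm: 0.045}
    sensitivity_cps_per_bq:
      w84_20: 1.000e-3
      w84_10: 0.500e-3
      w154_10: 4.153e-4
      w269_05: 2.694e-4
    background_fraction:
      w84_20: 0.32
      w84_10: 0.32
      w154_10: 0.45
      w269_05: 0.50
  HEGP:
    hole_diameter_mm: 4.0
    hole_length_mm: 66.0
    septal_thickness_mm: 1.8
    resolution: {fwhm0_mm: 5.0, slope_mm_per_mm: 0.054}
    sensitivity_cps_per_bq:
      w84_20: 0.995e-3
      w84_10: 0.4975e-3
      w154_10: 2.915e-4
      w269_05: 1.881e-4
    background_fraction:
      w84_20: 0.26
      w84_10: 0.26
      w154_10: 0.35
      w269_05: 0.40
  # generic high-count low-background reference-tracer camera model used by
  # the synthetic clinical correlation study (stands in for a Tc-99m-class
  # bone tracer acquisition; not a vendor reconstruction)
  REF:
    hole_diameter_mm: 1.5
    hole_length_mm: 35.0
    septal_thickness_mm: 0.2
    resolution: {fwhm0_mm: 4.0, slope_mm_per_mm: 0.040}
    sensitivity_cps_per_bq:
      ref: 1.0e-2
    background_fraction:
      ref: 0.05
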