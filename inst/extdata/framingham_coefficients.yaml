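# Sex-specific Cox-model constants for the Framingham general cardiovascular
# disease (CVD) 10-year risk profile, office-based (non-laboratory, BMI) and
# lipid-based (laboratory) variants.
#
# Provenance: transcribed from D'Agostino RB Sr. et al., "General
# cardiovascular risk profile for use in primary care: the Framingham Heart
# Study", Circulation 2008;117:743-753 (Tables 2 and 4 and the published
# baseline survival / mean linear predictor constants). The ideal_reference
# block is the same publication's "normal" risk-factor profile used to anchor
# heart-age (vascular-age) inversion.
#
# This file is data, not code: a checksum test locks it, and any edit must be
# re-validated against the source publication's worked example.
version: 1
models:
  non_lab:
    male:
      weights:
        ln_age: 3.11296
        ln_bmi: 0.79277
        ln_sbp_untreated: 1.85508
        ln_sbp_treated: 1.92672
        smoker: 0.70953
        diabetes: 0.53160
      baseline_survival_10y: 0.88431
      mean_linear_predictor: 23.9388
    female:
      weights:
        ln_age: 2.72107
        ln_bmi: 0.51125
        ln_sbp_untreated: 2.81291
        ln_sbp_treated: 2.88267
        smoker: 0.61868
        diabetes: 0.77763
      baseline_survival_10y: 0.94833
      mean_linear_predictor: 26.0145
  lab:
    male:
      weights:
        ln_age: 3.06117
        ln_total_chol: 1.12370
        ln_hdl: -0.93263
        ln_sbp_untreated: 1.93303
        ln_sbp_treated: 1.99881
        smoker: 0.65451
        diabetes: 0.57367
      baseline_survival_10y: 0.88936
      mean_linear_predictor: 23.9802
    female:
      weights:
        ln_age: 2.32888
        ln_total_chol: 1.20904
        ln_hdl: -0.70833
        ln_sbp_untreated: 2.76157
        ln_sbp_treated: 2.82263
        smoker: 0.52873
        diabetes: 0.69154
      baseline_survival_10y: 0.95012
      mean_linear_predictor: 26.1931
ideal_reference:
  sbp: 125.0
  bmi: 22.5
  total_chol: 180.0
  hdl: 45.0
  treated: false
  smoker: false
  diabetes: false
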