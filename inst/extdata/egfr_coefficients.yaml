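# Named eGFR coefficient sets for the piecewise power-law family
#   eGFR = intercept * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^slope
#          * age_decay^age * sex_multiplier [* race_multiplier]
# with Scr in mg/dL (creatinine stored in umol/L is divided by 88.4).
ckd_epi_2009:
  intercept: 141
  kappa:  {female: 0.7,    male: 0.9}
  alpha:  {female: -0.329, male: -0.411}
  slope: -1.209
  age_decay: 0.993
  female_multiplier: 1.018
  race_multiplier: 1.159   # applied only when race = "black"
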