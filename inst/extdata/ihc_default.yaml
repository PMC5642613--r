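# Default IHC fixture: 119 resected patients, two pan-B-cell markers
# counted in three regions (Tu tumor, Im infiltrative margin, Sd distant
# stroma); per-region mean and SEM set the count model (negative binomial:
# per-patient sd = SEM * sqrt(n)); survival is tied to CD20 Im-region
# high/low status; Kappa/IgM positivity depends on Im group.
n_patients: 119
count_family: negative_binomial
markers:
  CD20:
    Tu: {mean: 8.0, sem: 2.0}
    Im: {mean: 65.0, sem: 5.0}
    Sd: {mean: 25.0, sem: 3.0}
  CD79a:
    Tu: {mean: 13.0, sem: 3.0}
    Im: {mean: 62.0, sem: 7.0}
    Sd: {mean: 23.0, sem: 3.0}
survival_link:
  marker: CD20
  region: Im
  hr_high: 0.45            # hazard(Im-high) / hazard(Im-low); < 1 protective
  baseline_hazard: 0.0147  # events per month, Im-low group (median ~47 mo)
  censor_time: 120
positivity_link:           # P(Kappa or IgM positive | Im group), per region
  high: {Tu: 0.85, Im: 0.90, Sd: 0.30}
  low:  {Tu: 0.10, Im: 0.10, Sd: 0.15}
covariate_link:
  p_female: 0.22
  age_mean: 65
  age_sd: 9
  p_cirrhosis_high: 0.75   # cirrhosis enriched in Im-high patients
  p_cirrhosis_low: 0.45
  p_hep_b: 0.25
  p_hep_c: 0.2
  p_bridging: 0.3
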