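# Default two-platform validation fixture: 242 patients with paired
# tumor/non-tumor arrays; 10 of the 42 module genes stay co-regulated in
# tumor tissue and carry the overexpression shift in the "high" half of the
# cohort; survival is exponential with hazard(low) = baseline * true_hr and
# administrative censoring.
n_patients: 242
n_background_genes: 200
module_gene_ids: null      # null -> the 42 discovery-fixture module ids
retained_coregulated_count: 10
overexpression_effect: 1.5 # log2 tumor shift for retained genes, high group
high_fraction: 0.5
module_factor_sd: 1.0      # shared patient factor on retained genes (tumor)
noise_sd: 1.0
gene_mean: 8.0
gene_mean_sd: 1.0
true_hr: 1.5               # hazard(low) / hazard(high)
baseline_hazard: 0.012     # events per month, high group
censor_time: 60            # months, administrative
platforms:
  U133A2:
    shift: 0.0
    scale: 1.0
  HTU133A:
    shift: 0.6
    scale: 1.15
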