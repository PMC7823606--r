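seed: 42
simulate:
  n_subjects: 400
  n_snps: 12
  target_r2: 0.05
  causal_beta: 0.61
  baseline_prevalence: 0.35
maf_min: 0.005
info_min: 0.4
r2_threshold: 0.05
gwas_p: 5.0e-8
internal_p: 0.05
grs_weighting: weighted
n_boot: 200
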