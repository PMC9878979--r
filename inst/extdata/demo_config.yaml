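# Demo configuration for rodomics::run_all(). Any block omitted here falls
# back to default_config(); sizes are kept small so the full pipeline runs in
# well under a minute.
seed: 1
cohort:
  n_samples_per_group: 3
  section_um: [1600, 1600]
  fiber_pitch_um: 70
  rod_prevalence_by_group: {iNM: 0.53, SLONM: 0.11}
  size_ratio_by_group: {iNM: 1.12, SLONM: 0.60}
omics:
  n_features: 800
  n_per_group: 8
  frac_affected: 0.05
  effect_log2fc: 3
  censor_quantile: 0.10
gsea:
  n_perm: 200
ig:
  min_unique_peptides: 2
  alpha: 0.05
integration:
  n_shared_targets: 3
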