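# Example progression scenario: a wild type, a fast-progressing mutant and
# a slow overexpressor, at the package's baseline kinetics.
stage_rates: [0.14, 0.14, 0.14, 0.14, 0.14, 0.14, 0.14]   # per-hour exit rates, stages I..VII
genotype_multipliers:
  Col0: 1.0
  myb_mutant: 1.5
  MYB_OE: 0.67
initiation_intensity: 2.0        # expected LRP initiations per cm of PR
pr_length_mean_cm: 5.0
pr_length_sd_cm: 1.0
initiation_lag_h_mean: 6.0       # induced assay: mean stimulus-to-initiation delay
observation_times_h: [18, 42]
n_roots: 30
root_age_h: 96
seed: 7
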