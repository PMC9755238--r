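# Example simulate-mode pipeline configuration (scaled-down cohort).
seed: 42
n_term_pool: 120
n_term_spectrum: 100
n_longitudinal: 30
n_dwi: 40
q_threshold: 0.05
cohort:
  n_preterm: 40
  n_term: 40
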