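seed: 1
outdir: ferroscope_demo
simulate:
  enabled: true
  n_genes: 220
  n_cells: 400
  rho_planted: 0.5
score:
  enabled: true
  method: module
tfactivity:
  enabled: true
  min_overlap: 5
vko:
  enabled: true
  regulator: NFE2L2
  rho_min: 0.1
  p_max: 0.05
  min_cells: 5
survival:
  enabled: true
  n_subjects: 300
  effect_scale: 1.0
  censoring_rate: 0.3
spatial:
  enabled: true
  n_spots_side: 8
  gradient_high: 4
  gradient_low: 2
  k: 6
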