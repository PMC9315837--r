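# Frontal IgG capture on a 5-layer affinity-membrane stack:
# measured geometry, extra-column volumes, bi-Langmuir equilibrium and
# dispersivity for the experimental system.
schema_version: 1
column:
  thickness_cm: 0.1
  area_cm2: 3.8
  porosity: 0.545
  n_layers: 5
conditions:
  flowrate_ml_min: 1
  c0_mg_ml: 0.48
isotherm:
  variant: bi_langmuir
  q_m_irr: 4.75
  k_d_irr: 0
  q_m_rev: 7.00
  k_d_rev: 1.15
extra_column:
  v_cstr_ml: 0.69
  v_pfr_intercept_ml: 1.753
  v_pfr_slope_ml_per_ml_min: 0.025
dispersion:
  alpha_cm: 0.104
numerics:
  n_cells: 400
  delta_mg_ml: 1.0e-3
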