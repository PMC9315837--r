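# Polydisperse parallel-pore model of a single commercial membrane disc
# (2.2 cm diameter, 275 um thick, 80% porosity, 1.5 um mean pore radius)
# with a truncated Gaussian pore-size distribution.
schema_version: 1
column:
  thickness_cm: 275.0e-4
  diameter_cm: 2.2
  porosity: 0.80
  n_layers: 1
conditions:
  flowrate_ml_min: 1
psd:
  mu_um: 1.50
  sigma_um: 0.10
  rmin_um: 0.50
  rmax_um: 6.50
  theta: 1.0e-5
  n_bins: 600
moments:
  epsilon_in_moments: false
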