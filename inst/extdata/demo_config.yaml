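# Small demonstration configuration: 4 regions x 12 years, ~2,000 children,
# short MCMC runs. Intended for examples and quick end-to-end checks; the
# package defaults (default_config()) describe the full national-scale
# setting.
seed: 42
output_dir: "mortsmooth_demo"
input: simulate
adjacency:
  regions: [North, East, South, West]
  edges:
    - [North, East]
    - [East, South]
    - [South, West]
    - [West, North]
truth:
  mu: -2.75
  trend: -0.03
  temporal_order: 2
  years: [2010, 2021]
  variances: {alpha: 0.002, gamma: 0.0004, theta: 0.004, phi: 0.03, delta: 0.002}
design:
  clusters_per_stratum: 10
  women_per_cluster: 10
  births_per_woman_mean: 2.5
  urban_share: 0.3
  births_lead_years: 5
fanova:
  n_perm: 300
  level: 0.05
  smoothed: true
  lambda: gcv
model:
  n_iter: 2000
  n_burn: 500
  thin: 3
forecast:
  horizon_to: 2030
sdg_threshold: 25
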