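# Demo pipeline configuration: a small cis region with two purely
# protein-mediated lipid mediators and a binary cardiovascular outcome,
# four simulated compounds, and the full simulate -> mr -> meta -> concord
# chain. Every unset key falls back to a default that is echoed into the
# run manifest.
seed: 42
gwas:
  m: 30
  ld_rho: 0.8
  n_exposure: 4000
  n_outcome: 8000
  n_reference: 2000
  theta: 0.15
  outcome_prevalence: 0.1
instruments:
  maf_min: 0.01
  f_min: 15
  r2_max: 0.40
mr:
  prune: true
  direction: decrease
concordance:
  floor: 1.0e-60
  transform: sqrt_signed
  metric: euclidean
  linkage: complete
stages: [simulate, mr, meta, concord]
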