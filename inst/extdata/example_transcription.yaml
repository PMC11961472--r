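# Example coefficient-transcription file for tailorcut::transcribe_paper_models().
# All values here are SYNTHETIC stand-ins for illustration; replace them with
# the fitted coefficients of your own analysis (or a published solution) to
# reproduce that analysis exactly.
items: [x1, x2, x3, x4, x5, x6]
loadings:
  pq: {x1: 0.62, x2: 0.71, x3: 0.58}
  nq: {x4: 0.55, x5: 0.68, x6: 0.61}
residual_variances:
  x1: 0.62
  x2: 0.50
  x3: 0.66
  x4: 0.70
  x5: 0.54
  x6: 0.63
factor_covariance: 0.30
"n": 474   # quoted: bare y/n keys read as booleans under YAML 1.1
n_reps: 500
master_seed: 20474
estimator: MLR
margins:
  skewness: [-0.4, -0.4, -0.4, -0.4, -0.4, -0.4]
  excess_kurtosis: [-0.2, -0.2, -0.2, -0.2, -0.2, -0.2]
h1:
  type: residual_correlations
  r: 0.5
  pairs:
    - [x1, x2]
    - [x4, x6]
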