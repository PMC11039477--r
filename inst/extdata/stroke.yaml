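name: stroke
notes: >
  Thrombolysis delay-time monitoring in stroke care.  Responses are the
  base-10 logs of onset-to-needle (y1) and door-to-needle (y2) times in
  minutes, regressed on age (x1, years), sex (x2, 0 male / 1 female) and
  stroke severity (x3, NIHSS score).  Coefficients and error covariance are
  the fitted Phase-I values.  There is no fixed design: covariates vary
  patient by patient, so stream generation draws them from the synthetic
  distributions below (the source register data are restricted; these
  defaults affect only synthetic demonstrations, not the chart math).
q: 3
p: 2
B:
  - [2.0457, 1.6797]
  - [0.00084, -0.00079]
  - [0.01597, 0.01558]
  - [-0.0045, -0.0032]
Sigma:
  - [0.0399, 0.0207]
  - [0.0207, 0.0743]
designs: {}
chart:
  lam: 0.2
  k1: 1.0
  k2: 1.5
  tau_design: 1.1
covariates:
  age:
    dist: normal
    mean: 72.0
    sd: 10.0
    min: 18.0
    max: 100.0
  sex:
    dist: bernoulli
    prob: 0.5
  severity:
    dist: gamma
    shape: 2.0
    scale: 4.0
    min: 0.0
    max: 42.0
response_scale: log10
design:
  n1: 4
  n2: 8
  En: 6
  t2: 1.0
  Et: 2.0
  alpha1: 0.004
  Ealpha: 0.005
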