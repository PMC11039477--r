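name: p6_sim
notes: >
  Six-response, six-covariate scenario.  Only the coefficient matrix is
  published for this case: the n = 8 and n = 16 design matrices are not
  printed ("to save space") and neither is the error covariance, so the
  design map is empty (the user must supply X) and Sigma is a SYNTHETIC
  stand-in with unit variances and the stated common correlation 0.5.
q: 6
p: 6
B:
  - [-0.05, 0.48, 0.37, 0.04, 0.09, 0.09]
  - [10.0, 0.24, 0.09, 0.0, -0.021, 0.04]
  - [-0.01, 21.01, 0.01, 0.0, 0.0, 0.0]
  - [-0.03, -0.09, 6.81, 0.0, 0.01, -0.01]
  - [0.26, 0.03, 0.04, 10.53, 0.02, 0.18]
  - [0.0, -0.12, 0.02, -0.47, 7.0, -0.34]
  - [0.03, 0.01, -0.03, 0.21, -0.34, 11.46]
Sigma:
  - [1.0, 0.5, 0.5, 0.5, 0.5, 0.5]
  - [0.5, 1.0, 0.5, 0.5, 0.5, 0.5]
  - [0.5, 0.5, 1.0, 0.5, 0.5, 0.5]
  - [0.5, 0.5, 0.5, 1.0, 0.5, 0.5]
  - [0.5, 0.5, 0.5, 0.5, 1.0, 0.5]
  - [0.5, 0.5, 0.5, 0.5, 0.5, 1.0]
designs: {}
chart:
  lam: 0.2
  k1: 1.0
  k2: 1.5
  tau_design: 1.1
design:
  n1: 8
  n2: 16
  En: 12
  t2: 0.1
  Et: 1.0
  alpha1: 0.004
  Ealpha: 0.005
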