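name: p2_sim
notes: >
  Two-response, two-covariate simulation scenario: y1 = 3 + 2 x1 + x2 + e1,
  y2 = 2 + x1 + x2 + e2, error covariance [[1, 0.5], [0.5, 1]].  Fixed
  design matrices for n = 4 (FP and VP region 1) and n = 8 (VP region 2).
q: 2
p: 2
B:
  - [3.0, 2.0]
  - [2.0, 1.0]
  - [1.0, 1.0]
Sigma:
  - [1.0, 0.5]
  - [0.5, 1.0]
designs:
  "4":
    - [1, 2, 1]
    - [1, 4, 2]
    - [1, 6, 3]
    - [1, 8, 2]
  "8":
    - [1, 2, 1]
    - [1, 4, 2]
    - [1, 6, 3]
    - [1, 8, 2]
    - [1, 9, 3]
    - [1, 10, 1]
    - [1, 9, 2]
    - [1, 11, 1]
chart:
  lam: 0.2
  k1: 1.0
  k2: 1.5
  tau_design: 1.1
shift_grid:
  intercept:
    - [0.0, 0.0]
    - [0.1, 0.1]
    - [0.2, 0.0]
    - [0.2, 0.2]
    - [0.5, 0.5]
    - [1.0, 1.0]
  slope1:
    - [0.0, 0.0]
    - [0.02, 0.02]
    - [0.05, 0.0]
    - [0.05, 0.05]
    - [0.1, 0.1]
    - [0.2, 0.2]
  slope2:
    - [0.0, 0.0]
    - [0.05, 0.05]
    - [0.1, 0.0]
    - [0.1, 0.1]
    - [0.2, 0.2]
    - [1.0, 1.0]
  tau: [1.0, 1.1, 1.3, 2.0]
design:
  n1: 4
  n2: 8
  En: 6
  t2: 0.1
  Et: 1.0
  alpha1: 0.004
  Ealpha: 0.005
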