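name: scenario2
group_sizes:
- 200
- 50
visit_windows:
- - 170.0
  - 200.0
- - 350.0
  - 390.0
- - 710.0
  - 770.0
day_to_month: 0.032854209446
markers:
  albumin:
    name: albumin
    family: gaussian
    random_intercept: yes
    random_slope: yes
    fixed_slope: no
  lbili:
    name: lbili
    family: gaussian
    random_intercept: yes
    random_slope: yes
    fixed_slope: no
groups:
- mean:
    albumin:int: 3.0
    albumin:slope: 0.0
    lbili:int: 1.0
    lbili:slope: 0.0
  sd:
    albumin:int: 0.065
    albumin:slope: 0.00776
    lbili:int: 0.0112
    lbili:slope: 0.0149
  corr:
  - - albumin:int
    - albumin:slope
    - -0.0646
  - - albumin:int
    - lbili:int
    - -0.197
  - - albumin:slope
    - lbili:int
    - 0.00157
  - - albumin:int
    - lbili:slope
    - 0.211
  - - albumin:slope
    - lbili:slope
    - -0.233
  - - lbili:int
    - lbili:slope
    - -0.175
  residual_sd:
    albumin: 0.314
    lbili: 0.395
- mean:
    albumin:int: 3.0
    albumin:slope: 0.0
    lbili:int: 1.0
    lbili:slope: 0.0
  sd:
    albumin:int: 0.065
    albumin:slope: 0.00776
    lbili:int: 0.0112
    lbili:slope: 0.0149
  corr:
  - - albumin:int
    - albumin:slope
    - -0.0646
  - - albumin:int
    - lbili:int
    - -0.197
  - - albumin:slope
    - lbili:int
    - 0.00157
  - - albumin:int
    - lbili:slope
    - 0.211
  - - albumin:slope
    - lbili:slope
    - -0.233
  - - lbili:int
    - lbili:slope
    - -0.175
  residual_sd:
    albumin: 0.159
    lbili: 0.169
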