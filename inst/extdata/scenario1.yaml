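name: scenario1
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
  platelet:
    name: platelet
    family: poisson
    random_intercept: yes
    random_slope: yes
    fixed_slope: no
  bvm:
    name: bvm
    family: bernoulli
    random_intercept: yes
    random_slope: no
    fixed_slope: yes
groups:
- mean:
    albumin:int: 3.69
    albumin:slope: -0.00683
    lbili:int: 0.0213
    lbili:slope: 0.00994
    platelet:int: 5.54
    platelet:slope: -0.00429
    bvm:int: -2.54
  sd:
    albumin:int: 0.264
    albumin:slope: 0.00776
    lbili:int: 0.845
    lbili:slope: 0.0149
    platelet:int: 0.345
    platelet:slope: 0.0151
    bvm:int: 1.88
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
  - - albumin:int
    - platelet:int
    - 0.191
  - - albumin:slope
    - platelet:int
    - -0.257
  - - lbili:int
    - platelet:int
    - 0.247
  - - lbili:slope
    - platelet:int
    - -0.169
  - - albumin:int
    - platelet:slope
    - 0.109
  - - albumin:slope
    - platelet:slope
    - -0.26
  - - lbili:int
    - platelet:slope
    - -0.187
  - - lbili:slope
    - platelet:slope
    - 0.125
  - - platelet:int
    - platelet:slope
    - 0.0614
  - - albumin:int
    - bvm:int
    - -0.348
  - - albumin:slope
    - bvm:int
    - 0.227
  - - lbili:int
    - bvm:int
    - 0.27
  - - lbili:slope
    - bvm:int
    - 0.00813
  - - platelet:int
    - bvm:int
    - -0.248
  - - platelet:slope
    - bvm:int
    - -0.0803
  residual_sd:
    albumin: 0.318
    lbili: 0.338
  fixed:
    bvm:
    - 0.0146
- mean:
    albumin:int: 3.39
    albumin:slope: -0.0144
    lbili:int: 1.23
    lbili:slope: 0.0238
    platelet:int: 5.46
    platelet:slope: -0.0114
    bvm:int: -0.681
  sd:
    albumin:int: 0.264
    albumin:slope: 0.00776
    lbili:int: 0.845
    lbili:slope: 0.0149
    platelet:int: 0.345
    platelet:slope: 0.0151
    bvm:int: 1.88
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
  - - albumin:int
    - platelet:int
    - 0.191
  - - albumin:slope
    - platelet:int
    - -0.257
  - - lbili:int
    - platelet:int
    - 0.247
  - - lbili:slope
    - platelet:int
    - -0.169
  - - albumin:int
    - platelet:slope
    - 0.109
  - - albumin:slope
    - platelet:slope
    - -0.26
  - - lbili:int
    - platelet:slope
    - -0.187
  - - lbili:slope
    - platelet:slope
    - 0.125
  - - platelet:int
    - platelet:slope
    - 0.0614
  - - albumin:int
    - bvm:int
    - -0.348
  - - albumin:slope
    - bvm:int
    - 0.227
  - - lbili:int
    - bvm:int
    - 0.27
  - - lbili:slope
    - bvm:int
    - 0.00813
  - - platelet:int
    - bvm:int
    - -0.248
  - - platelet:slope
    - bvm:int
    - -0.0803
  residual_sd:
    albumin: 0.314
    lbili: 0.396
  fixed:
    bvm:
    - 0.0481
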