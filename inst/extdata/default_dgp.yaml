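'n': 4681
seed: 1
outcomes:
- vat
- sat
- fatpct
- leanpct
- weight
marginals:
  age:
    mean: 63.4
    sd: 7.4
  hei:
    mean: 65.8
    sd: 10.6
  alcohol:
    mean: 1.9
    sd: 4.4
  met:
    mean: 12.0
    sd: 10.0
  cesd:
    mean: 0.12
    sd: 0.08
  log_energy:
    mean: 7.293
    sd: 0.42
  rho:
    hei: 0.65
    alcohol: 0.7
    met: 0.6
    cesd: 0.6
    log_energy: 0.7
categorical_probs:
  race:
    aian: 0.0105
    asian: 0.0048
    black: 0.1111
    white: 0.8673
    multi: 0.0063
  income:
    lt35k: 0.523
    35to75k: 0.347
    ge75k: 0.13
  educ:
    hs_or_less: 0.3007
    some_college: 0.3558
    college: 0.1822
    graduate: 0.1613
  marital:
    never: 0.039
    divorced: 0.138
    widowed: 0.194
    married: 0.618
    marriage_like: 0.011
  sleep:
    le5: 0.09
    h6: 0.267
    h7: 0.38
    h8: 0.216
    ge9: 0.047
  smoking:
    never: 0.5
    former: 0.344
    current: 0.156
binary_probs:
  hispanic: 0.074
  diabetes: 0.062
  cancer: 0.095
smoking_transition:
  never:
    never: 0.97
    former: 0.02
    current: 0.01
  former:
    never: 0.02
    former: 0.93
    current: 0.05
  current:
    never: 0.01
    former: 0.14
    current: 0.85
exposure:
  shift: 0.45
  mu: -0.878
  sigma: 0.6213
  rho_z: 0.5
  coefs:
    hei: 0.015
    met: 0.012
    age: -0.004
    log_energy: 0.9
  smoking_coefs:
    never: 0.0
    former: -0.03
    current: -0.1
outcome_params:
  mean:
    vat: 153.6
    sat: 358.5
    fatpct: 43.2
    leanpct: 53.9
    weight: 70.1
  sd:
    vat: 81.7
    sat: 135.2
    fatpct: 7.2
    leanpct: 7.5
    weight: 15.0
  loading:
    vat: 60.0
    sat: 100.0
    fatpct: 5.5
    leanpct: -5.5
    weight: 10.0
  gamma:
    vat:
      hei: -1.5
      met: -1.5
      age: 0.8
      diabetes: 20.0
      cesd: 30.0
    sat:
      hei: -2.5
      met: -2.5
      age: 1.33
      diabetes: 33.0
      cesd: 50.0
    fatpct:
      hei: -0.1
      met: -0.12
      age: 0.05
      diabetes: 1.2
      cesd: 2.0
    leanpct:
      hei: 0.1
      met: 0.12
      age: -0.05
      diabetes: -1.2
      cesd: -2.0
    weight:
      hei: -0.15
      met: -0.2
      age: -0.05
      diabetes: 3.0
      cesd: 3.0
  rho: 0.7
  effect:
    vat: -10.0
    sat: -19.3
    fatpct: -0.76
    leanpct: 0.69
    weight: -1.91
  effect_a0:
    vat: -5.0
    sat: -9.65
    fatpct: -0.38
    leanpct: 0.345
    weight: -0.955
  a_ref: 1.0
  resid_sd:
    vat: 50.3290294
    sat: 82.3139912
    fatpct: 4.3336077
    leanpct: 4.8156158
    weight: 10.8514513
censoring_params:
  enabled: yes
  death:
    intercept: -3.3621359
    age: 0.06
    diabetes: 0.6
    cesd: 1.0
    a1: -0.15
  ltfu:
    intercept: -1.9449962
    age: 0.02
    cesd: 0.8
    current_smoker: 0.3
    a1: -0.1
clip_outcomes: yes
missing_protein_rate: 0.01
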