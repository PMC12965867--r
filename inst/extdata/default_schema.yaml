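exposure: a
outcomes:
- vat
- sat
- fatpct
- leanpct
- weight
covariates:
- name: age
  type: continuous
  time_varying: no
  transform: identity
- name: race
  type: categorical
  time_varying: no
  transform: identity
  levels:
  - aian
  - asian
  - black
  - white
  - multi
  collapse:
    other:
    - aian
    - asian
    - multi
- name: hispanic
  type: binary
  time_varying: no
  transform: identity
- name: income
  type: categorical
  time_varying: no
  transform: identity
  levels:
  - lt35k
  - 35to75k
  - ge75k
- name: educ
  type: categorical
  time_varying: no
  transform: identity
  levels:
  - hs_or_less
  - some_college
  - college
  - graduate
- name: marital
  type: categorical
  time_varying: no
  transform: identity
  levels:
  - never
  - divorced
  - widowed
  - married
  - marriage_like
  collapse:
    married:
    - married
    - marriage_like
- name: sleep
  type: categorical
  time_varying: no
  transform: identity
  levels:
  - le5
  - h6
  - h7
  - h8
  - ge9
- name: smoking
  type: categorical
  time_varying: yes
  transform: identity
  levels:
  - never
  - former
  - current
- name: diabetes
  type: binary
  time_varying: no
  transform: identity
- name: cancer
  type: binary
  time_varying: no
  transform: identity
- name: hei
  type: continuous
  time_varying: yes
  transform: identity
- name: alcohol
  type: continuous
  time_varying: yes
  transform: identity
- name: met
  type: continuous
  time_varying: yes
  transform: identity
- name: cesd
  type: continuous
  time_varying: yes
  transform: identity
- name: energy
  type: continuous
  time_varying: yes
  transform: log
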