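rules:
- algorithm_id: hypokalemia
  rule: threshold
  parameters:
  - K
  critical:
  - parameter: K
    op: <
    threshold: 2.5
    units: mmol/L
  warning:
  - parameter: K
    lo: 2.5
    hi: 3.0
  ttc_hours: 6.0
  diagnosis: Hypokalemia
  active: yes
  annotations:
    severe: 2.0
    life_threatening: 1.9
- algorithm_id: hypercalcemia
  rule: threshold
  parameters:
  - CA_TOTAL
  - CA_IONIZED
  critical:
  - parameter: CA_TOTAL
    op: '>'
    threshold: 3.5
    units: mmol/L
  - parameter: CA_IONIZED
    op: '>'
    threshold: 2.0
    units: mmol/L
  warning:
  - parameter: CA_TOTAL
    lo: 3.0
    hi: 3.5
  - parameter: CA_IONIZED
    lo: 1.6
    hi: 2.0
  ttc_hours: 12.0
  diagnosis: Hypercalcemia
  active: yes
- algorithm_id: hyponatremia
  rule: threshold
  parameters:
  - NA
  critical:
  - parameter: NA
    op: <
    threshold: 120.0
    units: mmol/L
  warning:
  - parameter: NA
    lo: 120.0
    hi: 125.0
  ttc_hours: 12.0
  diagnosis: Hyponatremia
  active: yes
- algorithm_id: hyperlactatemia
  rule: threshold
  parameters:
  - LACTATE
  critical:
  - parameter: LACTATE
    op: '>'
    threshold: 4.0
    units: mmol/L
  warning:
  - parameter: LACTATE
    lo: 2.5
    hi: 4.0
  ttc_hours: 6.0
  diagnosis: Hyperlactatemia
  active: yes
- algorithm_id: acute_kidney_injury
  rule: AKIN
  parameters:
  - CREATININE
  ttc_hours: immediate
  diagnosis: Acute kidney injury
  active: yes
- algorithm_id: sepsis
  rule: stub
  parameters:
  - PCT
  ttc_hours: immediate
  diagnosis: Sepsis
  active: no
- algorithm_id: myocardial_infarction
  rule: stub
  parameters:
  - TROPONIN_T
  ttc_hours: immediate
  diagnosis: Myocardial infarction
  active: no
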