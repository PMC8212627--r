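# small ward simulation: 10 patients over 3 days
n_patients: 10
duration_days: 3
rate_per_day: 2
critical_prevalence: 0.08
parameters: [K, NA, LACTATE, CREATININE]
response_delay_hours:
  CONTROL: {meanlog: 1.3862943611198906, sdlog: 0.5}      # median 4 h
  INTERVENTION: {meanlog: 0.4054651081081644, sdlog: 0.5} # median 1.5 h
seed: 7
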