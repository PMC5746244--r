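parameters:
- name: adherence
  low: 0.75
  high: 0.95
  units: probability/yr
  kind: probability
- name: coverage_65plus
  low: 0.43
  high: 0.72
  units: fraction
  kind: probability
- name: coverage_50_64
  low: 0.3
  high: 0.5
  units: fraction
  kind: probability
  note: placeholder range, not literature-sourced
- name: mortality_rate_65plus
  low: 9.4
  high: 15.6
  units: per 100,000/yr
  kind: rate_per_100k
- name: mortality_rate_50_64
  low: 0.8
  high: 2.2
  units: per 100,000/yr
  kind: rate_per_100k
  note: placeholder range, not literature-sourced
- name: hospitalization_rate_65plus
  low: 200.0
  high: 400.0
  units: per 100,000/yr
  kind: rate_per_100k
  note: placeholder range, not literature-sourced
- name: hospitalization_rate_50_64
  low: 40.0
  high: 100.0
  units: per 100,000/yr
  kind: rate_per_100k
  note: placeholder range, not literature-sourced
- name: illness_rate_65plus
  low: 4000.0
  high: 8000.0
  units: per 100,000/yr
  kind: rate_per_100k
  note: placeholder range, not literature-sourced
- name: illness_rate_50_64
  low: 3000.0
  high: 7000.0
  units: per 100,000/yr
  kind: rate_per_100k
  note: placeholder range, not literature-sourced
- name: efficacy_mortality
  low: 0.35
  high: 0.55
  units: fraction
  kind: probability
- name: efficacy_hospitalization
  low: 0.25
  high: 0.45
  units: fraction
  kind: probability
  note: placeholder range, not literature-sourced
- name: efficacy_illness
  low: 0.1
  high: 0.3
  units: fraction
  kind: probability
- name: qaly_weight_sickness
  low: 0.2
  high: 0.4
  units: QALY/event
  kind: qaly_weight
- name: qaly_weight_illness
  low: 0.004
  high: 0.012
  units: QALY/event
  kind: qaly_weight
  note: placeholder range, not literature-sourced - sick-time utility decrement times
    an illness duration of one to two weeks
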