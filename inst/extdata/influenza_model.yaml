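name: influenza_50plus
birth_cohort_size: 4000000.0
adherence_param: adherence
denominator: delivered
strata:
- label: 50-64
  person_years: 60000000.0
  coverage_param: coverage_50_64
  channels:
  - name: mortality
    incidence_param: mortality_rate_50_64
    efficacy_param: efficacy_mortality
    qaly_weight: 1.0
  - name: hospitalization
    incidence_param: hospitalization_rate_50_64
    efficacy_param: efficacy_hospitalization
    qaly_weight_param: qaly_weight_sickness
  - name: illness
    incidence_param: illness_rate_50_64
    efficacy_param: efficacy_illness
    qaly_weight_param: qaly_weight_illness
- label: 65+
  person_years: 50000000.0
  coverage_param: coverage_65plus
  channels:
  - name: mortality
    incidence_param: mortality_rate_65plus
    efficacy_param: efficacy_mortality
    qaly_weight: 1.0
  - name: hospitalization
    incidence_param: hospitalization_rate_65plus
    efficacy_param: efficacy_hospitalization
    qaly_weight_param: qaly_weight_sickness
  - name: illness
    incidence_param: illness_rate_65plus
    efficacy_param: efficacy_illness
    qaly_weight_param: qaly_weight_illness
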