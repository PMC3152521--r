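# Packaged parameters of the New Zealand insomnia treatment model.
# All dollar values NZD, GST-exclusive; currency year 2009 unless noted.
currency: NZD
currency_year: 2009
health_costs:
  personal_medical_services_m: 15313   # national spend, $M (2008)
  population_all_ages_m: 4.292         # population, millions (2008)
  insomnia_prevalence: 0.13            # proportion with insomnia symptoms
  cost_increase_mean: 0.18             # insomniac vs non-insomniac cost excess
  cost_increase_low: 0.05              # plausible literature range
  cost_increase_high: 0.25
scaling:
  at_risk_m: 2.317                     # population aged 20-59, millions
  prevalence: 0.13
  p_seek: 0.15                         # proportion of sufferers seeking care
utility:
  low: 0.0                             # conservative no-gain floor
  base: 0.157                          # mean utility difference
  high: 0.373                          # maximum observed utility difference
first_contact_raw:                     # survey percentages, first provider
  pharmacist: 16.5                     # consulted (multiple answers allowed,
  general_practitioner: 41.2           # hence no constraint to sum to 100)
  psychiatrist: 3.5
  psychologist: 7.1
  nurse: 3.5
  counsellor: 10.6
  herbalist: 8.2
  acupuncturist: 8.2
  hypnotist: 4.7
simulation:
  n_iterations: 10000
  default_fraction: 0.25               # symmetric +/-25% triangular ranges
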