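# Universal public finance of TB treatment in the hypothetical country
# 'Land': 10 million people, 2 million per income quintile. Identical to
# the scenario built by land_fixture().
name: land-tb-upf
currency: USD
strata_defaults:
  population: 2000000
  case_fatality: 0.20
  care_seeking: 0.40   # fraction of cases paying entirely out of pocket
  c_dm: 100
  c_dnm: 0
strata:
  - {label: I,   income: 300, incidence_per_100k: 400}
  - {label: II,  income: 470, incidence_per_100k: 300}
  - {label: III, income: 640, incidence_per_100k: 200}
  - {label: IV,  income: 810, incidence_per_100k: 100}
  - {label: V,   income: 980, incidence_per_100k: 0}
policy:
  name: upf-tb-treatment
  cov_baseline: 0.50
  cov_policy: 0.60
  effectiveness: 0.80
  unit_cost: 100       # implementer cost per covered case
  cov_costing: 0.50    # the implementer pays for 50% of cases
  crowd_out: 1         # public finance removes all out-of-pocket payment
  pe_convention: crowd_out
frp:
  metric: poverty
  poverty_line: 600
  risk_aversion: 3
  affected_fraction: 0.8   # exposed-case fraction for poverty counting
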