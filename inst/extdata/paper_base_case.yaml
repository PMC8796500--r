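# Base-case model configuration: lifetime cost-utility comparison of
# rituximab vs natalizumab in RRMS (2019 PPP$).
# Entries listed under not_from_paper are documented placeholders for
# quantities the source tables do not report (SPMS utilities, SPMS
# non-drug costs, cost dispersion); they are shared across arms so they
# cancel in incremental results.
name: paper_base_case
currency: "PPP$ 2019"
threshold:
  gdp_per_capita: 12547
  multiplier: 3
settings:
  start_age: 34
  max_age: 100
  discount_rate_costs: 0.058
  discount_rate_outcomes: 0.03
  survival_floor: 1.0e-6
  half_cycle_correction: false
  discount_first_cycle: false
  start_distribution:
    "EDSS 0-2.5": 1.0
    "EDSS 3-5.5": 0.0
    "EDSS 6-7.5": 0.0
    "EDSS 8-9.5": 0.0
transition_table:
  # annual living-to-living transition percentages; rows sum to ~100
  living_percent:
    "EDSS 0-2.5": [82.567, 15.93, 1.47, 0.033]
    "EDSS 3-5.5": [10.075, 59.73, 28.8, 1.4]
    "EDSS 6-7.5": [0.3, 5.5, 81.95, 12.25]
    "EDSS 8-9.5": [0.0, 0.1, 4.15, 95.75]
  # annual probability of death (%) from each living state
  death_percent:
    "EDSS 0-2.5": 1.343
    "EDSS 3-5.5": 1.718
    "EDSS 6-7.5": 2.685
    "EDSS 8-9.5": 5.45
arms:
  natalizumab:
    annual_relapse_prob: 0.265
    drug_cost_annual: 32942.24
    other_cost:
      "EDSS 0-2.5": 3115.84
      "EDSS 3-5.5": 3115.84
      "EDSS 6-7.5": 3000.0
      "EDSS 8-9.5": 3000.0
    utilities:
      "EDSS 0-2.5": 0.754
      "EDSS 3-5.5": 0.530
      "EDSS 6-7.5": 0.45
      "EDSS 8-9.5": 0.10
    utility_sd:
      "EDSS 0-2.5": 0.186
      "EDSS 3-5.5": 0.120
  rituximab:
    annual_relapse_prob: 0.104
    drug_cost_annual: 2038.51
    other_cost:
      "EDSS 0-2.5": 3360.77
      "EDSS 3-5.5": 3360.77
      "EDSS 6-7.5": 3000.0
      "EDSS 8-9.5": 3000.0
    utilities:
      "EDSS 0-2.5": 0.833
      "EDSS 3-5.5": 0.621
      "EDSS 6-7.5": 0.45
      "EDSS 8-9.5": 0.10
    utility_sd:
      "EDSS 0-2.5": 0.125
      "EDSS 3-5.5": 0.097
psa:
  n_iterations: 5000
  cost_cv: 0.2
  spms_utility_sd:
    "EDSS 6-7.5": 0.10
    "EDSS 8-9.5": 0.05
# observed mean annual societal costs per patient (2019 PPP$), by arm,
# category (DMC / DNMC / IC) and item
observed_annual_costs:
  natalizumab:
    DMC:
      "Physicians' Visits": 258.00
      "Main Medicines": 32942.24
      "Supplementary Medicines": 695.69
      "Laboratory Tests": 267.18
      "MRIs": 508.09
      "Physiotherapy & Other Services Costs": 0.00
      "Hospitalization & Surgeries": 241.60
    DNMC:
      "Transportation": 441.72
      "Accommodation": 53.14
      "Meals": 53.14
      "Purchasing Auxiliary Tools": 117.70
    IC:
      "Income Lost due to Outpatient Visits": 282.83
      "Income Lost due to Hospitalization": 79.27
      "Patient's Family Costs": 117.48
  rituximab:
    DMC:
      "Physicians' Visits": 89.90
      "Main Medicines": 2038.51
      "Supplementary Medicines": 421.64
      "Laboratory Tests": 220.63
      "MRIs": 1457.97
      "Physiotherapy & Other Services Costs": 647.27
      "Hospitalization & Surgeries": 56.04
    DNMC:
      "Transportation": 27.94
      "Purchasing Auxiliary Tools": 13.18
    IC:
      "Income Lost due to Outpatient Visits": 254.72
      "Income Lost due to Hospitalization": 64.40
      "Patient's Family Costs": 107.08
not_from_paper:
  - "arms/natalizumab/other_cost/EDSS 6-7.5"
  - "arms/natalizumab/other_cost/EDSS 8-9.5"
  - "arms/rituximab/other_cost/EDSS 6-7.5"
  - "arms/rituximab/other_cost/EDSS 8-9.5"
  - "arms/natalizumab/utilities/EDSS 6-7.5"
  - "arms/natalizumab/utilities/EDSS 8-9.5"
  - "arms/rituximab/utilities/EDSS 6-7.5"
  - "arms/rituximab/utilities/EDSS 8-9.5"
  - "psa/cost_cv"
  - "psa/spms_utility_sd/EDSS 6-7.5"
  - "psa/spms_utility_sd/EDSS 8-9.5"
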