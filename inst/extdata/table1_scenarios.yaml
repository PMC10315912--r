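# Intervention scenario library: five intervention approaches, twelve
# scenarios, and the two combination packages. All scenarios start in 2021
# and are maintained to 2050 after their scale-up window.
scenarios:
  # Intervention 1: lifestyle management applied to high-risk populations.
  # IRR 0.70 is the average of the evidence-based effect sizes 0.65 and 0.74.
  - id: lifestyle_obese
    label: Lifestyle management programmes for those categorized as obese
    uptake: 0.5
    adherence: 0.5
    ramp: [2021, 2025]
    filter: {min_age: 20, max_age: 79, require_obese: true}
    effects:
      irr: 0.70
      evidence_irr: [0.65, 0.74]
  - id: lifestyle_age50
    label: Lifestyle management programmes for those aged 50 and over
    uptake: 0.5
    adherence: 0.5
    ramp: [2021, 2025]
    filter: {min_age: 50, max_age: 79}
    effects:
      irr: 0.70
      evidence_irr: [0.65, 0.74]
  - id: lifestyle_obese_35plus
    label: Lifestyle management programmes for those obese and aged 35 and over
    uptake: 0.5
    adherence: 0.5
    ramp: [2021, 2025]
    filter: {min_age: 35, max_age: 79, require_obese: true}
    effects:
      irr: 0.70
      evidence_irr: [0.65, 0.74]

  # Intervention 2: increasing use of different modes of active commuting.
  - id: public_transport
    label: Public transportation use
    uptake: 0.4
    adherence: 1.0
    ramp: [2021, 2030]
    bmi_shift: 0.51
    effects:
      obesity_prev_target: 0.509
      scope: total
      normalize_inactivity: true
  - id: cycling_walking
    label: Cycling or walking
    uptake: 0.2
    adherence: 1.0
    ramp: [2021, 2030]
    bmi_shift: 1.68
    effects:
      irr: 0.76
      obesity_prev_target: 0.504
      scope: total

  # Intervention 3: increasing consumption of healthy diets.
  - id: fruit_veg
    label: Consumption of fruits and vegetables
    uptake: 0.5
    adherence: 1.0
    ramp: [2021, 2030]
    effects:
      irr: 0.93
  - id: vegetables
    label: Consumption of vegetables
    uptake: 0.5
    adherence: 1.0
    ramp: [2021, 2030]
    effects:
      irr: 0.90
  - id: leafy_greens
    label: Consumption of green leafy vegetables
    uptake: 0.5
    adherence: 1.0
    ramp: [2021, 2030]
    effects:
      irr: 0.87
  - id: workplace_diet
    label: Workplace dietary modifications plus an educational intervention
    uptake: 0.5
    adherence: 1.0
    ramp: [2021, 2030]
    filter: {min_age: 20, max_age: 65}
    bmi_shift: 2.4
    effects:
      irr: 0.93
      obesity_prev_target: 0.348
      scope: covered

  # Intervention 4: subsidy and legislation.
  - id: subsidies_fv
    label: Subsidies on fruits and vegetables
    uptake: 0.2
    adherence: 1.0
    ramp: [2021, 2030]
    bmi_shift: 0.16
    effects:
      obesity_prev_target: 0.526
      scope: total
  - id: ssb_tax
    label: Taxation on sugar-sweetened beverages
    uptake: 0.2
    adherence: 1.0
    ramp: [2021, 2030]
    bmi_shift: 0.24
    effects:
      obesity_prev_target: 0.523
      scope: total
  - id: subsidies_ssb_tax
    label: Subsidies on fruits and vegetables plus taxation on SSB
    uptake: 0.2
    adherence: 1.0
    ramp: [2021, 2030]
    bmi_shift: 0.40   # additive effect of 0.16 and 0.24
    effects:
      obesity_prev_target: 0.516
      scope: total

packages:
  most_optimistic:
    - lifestyle_obese_35plus
    - cycling_walking
    - workplace_diet
    - subsidies_ssb_tax
  least_optimistic:
    - lifestyle_obese
    - public_transport
    - fruit_veg
    - subsidies_fv
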