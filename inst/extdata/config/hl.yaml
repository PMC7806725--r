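# Hyperlipidemia decision-point criteria (AHA/ACC-style)
disease: HL
study_period: ["2008-01-01", "2018-12-31"]
dp_rule: diagnosis_then_lab
diagnosis_codes: [hl_dx]
lab: {code: ldl, op: ">", threshold: 130}
lookback_days: 420
analytes:
  - {code: ldl, op: ">", threshold: 130}
min_age: 18
age_code: age
pregnancy_codes: [pregnancy_dx]
pregnancy_exclusion_days: 365
refill_codes: [refill]
decision_buffer_days: 14
followup: {min_days: 30, max_days: 450, changed_min_days: 30}
treatment_universe:
  - {code: simvastatin, ingredient: Simvastatin, class: Statin}
  - {code: atorvastatin, ingredient: Atorvastatin, class: Statin}
  - {code: pravastatin, ingredient: Pravastatin, class: Statin}
  - {code: rosuvastatin, ingredient: Rosuvastatin, class: Statin}
  - {code: ezetimibe, ingredient: Ezetimibe, class: Cholesterol_Absorption_Inhibitor}
filter_variables: [med_simvastatin, med_atorvastatin, med_pravastatin,
                   med_rosuvastatin, med_ezetimibe, age60]
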