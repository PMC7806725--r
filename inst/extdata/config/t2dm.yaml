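# Type 2 diabetes decision-point criteria (ADA-style)
disease: T2DM
study_period: ["2008-01-01", "2018-12-31"]
dp_rule: diagnosis_then_lab
diagnosis_codes: [t2dm_dx]
lab: {code: hba1c, op: ">=", threshold: 7.0}
lookback_days: 365
analytes:
  - {code: hba1c, op: ">=", threshold: 7.0}
min_age: 18
age_code: age
pregnancy_codes: [pregnancy_dx]
pregnancy_exclusion_days: 365
refill_codes: [refill]
decision_buffer_days: 14
followup: {min_days: 90, max_days: 365, changed_min_days: 90}
treatment_universe:
  - {code: metformin, ingredient: Metformin, class: Biguanides}
  - {code: glyburide, ingredient: Glyburide, class: Sulfonylurea}
  - {code: glipizide, ingredient: Glipizide, class: Sulfonylurea}
  - {code: glimepiride, ingredient: Glimepiride, class: Sulfonylurea}
  - {code: sitagliptin, ingredient: Sitagliptin, class: DPP4}
  - {code: glargine, ingredient: Glargine, class: Insulin}
filter_variables: [med_metformin, med_glyburide, med_glipizide,
                   med_glimepiride, med_sitagliptin, med_glargine, age60]
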