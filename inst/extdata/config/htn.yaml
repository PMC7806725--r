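# Hypertension decision-point criteria (JNC-7/JNC-8-style)
disease: HTN
study_period: ["2004-01-01", "2018-12-31"]
dp_rule: consecutive_uncontrolled_pair
analytes:
  - {code: sbp, op: ">=", threshold: 140}
  - {code: dbp, op: ">=", threshold: 90}
max_separation_days: 365
min_age: 18
age_code: age
pregnancy_codes: [pregnancy_dx]
pregnancy_exclusion_days: 365
refill_codes: [refill]
decision_buffer_days: 14
followup: {min_days: 1, max_days: 365, changed_min_days: 14}
treatment_universe:
  - {code: lisinopril, ingredient: Lisinopril, class: ACEI}
  - {code: hydrochlorothiazide, ingredient: Hydrochlorothiazide, class: Thiazide}
  - {code: chlorthalidone, ingredient: Chlorthalidone, class: Thiazide}
  - {code: amlodipine, ingredient: Amlodipine, class: CCB}
  - {code: losartan, ingredient: Losartan, class: ARB}
  - {code: metoprolol, ingredient: Metoprolol, class: Beta_Blocker}
filter_variables: [med_lisinopril, med_hydrochlorothiazide, med_chlorthalidone,
                   med_amlodipine, med_losartan, med_metoprolol, age60]
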