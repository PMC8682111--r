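name,low,high
ascvd_diabetes_ckd,28,43
ascvd_diabetes_no_ckd,26,29
ascvd_ckd,34,35
recent_acs,32,32
cad_uncontrolled_risk_factors,28,41
cad_peripheral_artery_disease,43,55
cad_age_65_plus,21,54
ischemic_stroke_male,31,31
cad_familial_hypercholesterolemia,41,41
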