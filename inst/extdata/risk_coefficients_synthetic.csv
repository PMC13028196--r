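term,estimate
(Intercept),-3.00
age,0.010
sex_female,0.05
total_drug_count,0.02
gld_count,0.05
su_count,0.60
insulin_count,3.20
premixed_insulin_use,0.30
antidepressant_use,0.20
insulin_duration_years,0.05
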