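metric,count,total
cohort_size,25057,25057
net5y_no_change,16765,25057
net5y_intensification,5314,25057
net5y_deintensification,2978,25057
high_risk,6492,25057
low_risk,18565,25057
metformin_monotherapy,10315,25057
su_non_insulin_combination,6623,25057
monotherapy,11932,25057
combination_therapy,13125,25057
female,12067,25057
male,12990,25057
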