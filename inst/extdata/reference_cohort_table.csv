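cohort,zone,n_total,n_high,n_low,accuracy_pct,sensitivity_pct,specificity_pct,ppv_pct,npv_pct
training,ENH,35,22,13,82.9,86.4,76.9,86.4,76.9
training,BAT,25,5,20,88,80,90,66.7,94.7
training,Both,60,27,33,85.0,85.2,84.8,82.1,87.5
validation,ENH,14,7,7,78.6,100,57.1,70,100
validation,BAT,8,2,6,87.5,100,83.3,66.7,100
validation,Both,22,9,13,81.8,100,69.2,69.2,100
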