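term,coefficient
intercept,-339.206
ce_ug_ml,2.476
v_mean_T1,-0.281
f_mean_T1,-5.422
f_median_T1,3.234
p_bandwidth_T1,0.116
spectral_entropy_T1,1441.537
f_mean_T2,0.074
spectral_entropy_T2,-38.100
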