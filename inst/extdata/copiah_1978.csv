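study_id,sex,age_lo,age_hi,cases,population
copiah,male,40,65,4,2473
copiah,male,65,75,4,948
copiah,male,75,Inf,5,472
copiah,female,40,65,3,3016
copiah,female,65,75,8,1235
copiah,female,75,Inf,7,781
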