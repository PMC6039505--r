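sex,age_lo,age_hi,count
male,40,65,50137484
male,65,75,10096519
male,75,Inf,7266441
female,40,65,52242925
female,65,75,11616910
female,75,Inf,11288114
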