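algorithm,tp,fp,fn,tn
standard,210,948,NA,NA
age_adjusted,165,246,45,702
years,150,222,60,726
perc,207,933,3,15
peged,186,183,24,765
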