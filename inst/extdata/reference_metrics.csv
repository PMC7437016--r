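algorithm,sensitivity,specificity,ppv,npv,plr,nlr,youden,accuracy,imaging,missed
standard,NA,NA,18.1,NA,NA,NA,NA,NA,1158,NA
age_adjusted,78.6,74.1,40.1,94.0,3.034,0.289,0.527,74.9,411,45
years,71.4,76.6,40.3,92.4,3.051,0.373,0.480,75.6,372,60
perc,98.6,1.6,18.2,83.3,1.002,0.875,0.002,19.2,1140,3
peged,88.6,80.7,50.4,97.0,4.591,0.141,0.693,82.1,369,24
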