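algorithm_a,algorithm_b,imaging_diff,imaging_diff_pct,missed_diff,missed_diff_pct
peged,standard,-789,-68.1,NA,NA
peged,age_adjusted,-42,-3.6,-21,-1.8
peged,years,-3,-0.3,-36,-3.1
peged,perc,-771,-66.6,21,1.8
years,standard,-786,-67.9,NA,NA
years,age_adjusted,-39,-3.4,15,1.3
years,perc,-768,-66.3,57,4.9
age_adjusted,standard,-747,-64.5,NA,NA
age_adjusted,perc,-729,-63.0,42,3.6
perc,standard,-18,-1.6,NA,NA
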