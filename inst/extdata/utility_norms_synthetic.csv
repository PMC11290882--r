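age_low,age_high,sex,utility
16,24,male,0.94
16,24,female,0.94
25,34,male,0.93
25,34,female,0.93
35,44,male,0.91
35,44,female,0.91
45,54,male,0.85
45,54,female,0.85
55,64,male,0.80
55,64,female,0.81
65,74,male,0.78
65,74,female,0.78
75,110,male,0.75
75,110,female,0.71
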