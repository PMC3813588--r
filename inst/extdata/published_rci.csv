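analysis,round,sample_n,analyzed_n,rci,ci_low,ci_high
complete case,2000,6179,4156,0.29,0.22,0.36
complete case,2007,6680,4291,0.16,0.13,0.20
multiple imputation,2000,6179,5079,0.32,0.24,0.41
multiple imputation,2007,6680,5560,0.20,0.15,0.25
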