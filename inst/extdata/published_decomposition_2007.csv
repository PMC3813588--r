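contributor,beta,elasticity,concentration_index,contribution_pct,ci_low_pct,ci_high_pct
Log per capita expenditures,0.1,3.09,0.03,52,33,70
Use improved sanitation,0.09,0.14,0.13,12,6,18
Mother attended high school,0.1,0.09,0.16,9,4,13
Father attended university,0.1,0.02,0.57,9,2,15
Mother attended university,0.07,0.01,0.64,5,-2,11
Has electricity,0.25,0.6,0.01,5,3,70
Living in rural,-0.03,-0.05,-0.09,3,-1,7
Child is attending school,0.09,0.22,0.02,2,0,4
Living in Java/Bali,0.14,0.29,0,0,0,0
Father's mental health scores,-0.01,-0.05,-0.03,1,0,2
Mother's mental health scores,0,-0.03,-0.03,1,0,2
Father attended high school,0.04,0.04,0.11,3,0,6
Father is working,-0.13,-0.31,0.01,-2,-3,-1
Mother is working,0.05,0.07,0.07,3,1,5
Use improved drinking water,0.04,0.05,0.09,3,0,6
Child is male,0.05,0.06,-0.01,0,-1,0
Residual,,0,0,-3,,
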