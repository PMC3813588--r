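contributor,beta,elasticity,concentration_index,contribution_pct,ci_low_pct,ci_high_pct
Log per capita expenditures,0.08,3.38,0.03,37,19,55
Use improved sanitation,0.14,0.21,0.26,18,11,26
Mother attended high school,0.18,0.16,0.33,18,11,24
Father attended university,0.12,0.03,0.67,7,0,14
Mother attended university,0.17,0.03,0.69,7,1,12
Has electricity,0.2,0.65,0.03,6,4,9
Living in rural,-0.07,-0.16,-0.1,6,2,9
Child is attending school,0.17,0.56,0.02,3,2,5
Living in Java/Bali,0.13,0.37,0.02,3,1,4
Father's mental health scores,-0.01,-0.04,-0.06,1,0,2
Mother's mental health scores,-0.01,-0.06,-0.03,1,2,9
Father attended high school,0,0,0.2,0,-4,5
Father is working,0.04,0.13,0.01,0,0,1
Mother is working,0.01,0.02,0.01,0,0,0
Use improved drinking water,0,0,0.16,0,-5,5
Child is male,0.1,0.19,-0.02,-1,-2,-1
Residual,,0,0,-5,,
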