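contributor,change_in_inequality,change_in_elasticity,total,percent
Mother attended high school,-0.02,-0.02,-0.04,27
Use improved sanitation,-0.02,-0.02,-0.03,25
Log per capita expenditures,-0.02,-0.01,-0.02,18
Living in rural,0.00,-0.01,-0.01,8
Mother attended university,0.00,-0.01,-0.01,8
Has electricity,-0.01,0.00,-0.01,7
Father attended university,0.00,-0.01,-0.01,5
Living in Java/Bali,-0.01,0.00,-0.01,5
Child is attending school,0.00,-0.01,-0.01,4
Father is working,0.00,0.00,0.00,3
Father's mental health scores,0.00,0.00,0.00,1
Mother's mental health scores,0.00,0.00,0.00,0
Residual,0.00,0.00,0.00,0
Father attended high school,0.00,0.01,0.00,-2
Child is male,0.00,0.00,0.00,-3
Mother is working,0.00,0.00,0.00,-3
Use improved drinking water,0.00,0.01,0.00,-3
Total,-0.07,-0.07,-0.14,100
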