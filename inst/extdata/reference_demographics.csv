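variable,level,n,pct,n_no_csad,pct_no_csad,n_csad,pct_csad
cohort,all,13359,100.0,12342,92.4,1017,7.6
sex,female,10717,80.2,9874,92.1,843,7.9
sex,male,2642,19.8,2468,93.4,174,6.6
marital,married,11598,86.8,10750,92.7,848,7.3
marital,unmarried,83,0.6,76,91.6,7,8.4
marital,widowed,1474,11.0,1335,90.6,139,9.4
marital,divorced,204,1.5,181,88.7,23,11.3
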