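variable,group,mean,sd
age,all,69.9,10.2
age,no_csad,70.1,10.3
age,csad,68.4,9.8
multimorbidity,all,6.4,4.8
multimorbidity,no_csad,6.3,4.7
multimorbidity,csad,7.3,4.9
multimorbidity,male,8.3,5.3
multimorbidity,female,5.9,4.5
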