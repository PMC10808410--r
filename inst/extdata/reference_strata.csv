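stratum,n
total,13359
female,10717
male,2642
age_50_59,2173
age_60_69,4453
age_70_79,4300
age_80plus,2433
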