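code,n_total,pct_total,n_female,pct_female,rank_female,n_male,pct_male,rank_male,p_sex,n_50_59,pct_50_59,rank_50_59,n_60_69,pct_60_69,rank_60_69,n_70_79,pct_70_79,rank_70_79,n_80plus,pct_80plus,rank_80plus,p_age
I10,5869,43.9,4590,42.8,1,1279,48.4,1,<0.001,504,23.2,1,1591,35.7,1,2220,51.6,1,1554,63.9,1,<0.001
E11,2691,20.1,1964,18.3,4,727,27.5,2,<0.001,250,11.5,5,739,16.6,5,1031,24.0,2,671,27.6,6,<0.001
M51,2656,19.9,2160,20.2,2,496,18.8,8,0.111,398,18.3,3,930,20.9,2,913,21.2,3,415,17.1,13,<0.001
I70,2468,18.5,1790,16.7,6,678,25.7,4,<0.001,221,10.2,8,618,13.9,6,883,20.5,5,746,30.7,3,<0.001
K76,2462,18.4,1904,17.8,5,558,21.1,6,<0.001,402,18.5,2,838,18.8,4,768,17.9,7,454,18.7,9,0.69
M17,2331,17.4,2098,19.6,3,233,8.8,16,<0.001,312,14.4,4,835,18.8,3,884,20.6,4,300,12.3,14,<0.001
N28,2114,15.8,1531,14.3,7,583,22.1,5,<0.001,236,10.9,7,545,12.2,7,806,18.7,6,527,21.7,8,<0.001
I67,1890,14.1,1430,13.3,8,460,17.4,10,<0.001,144,6.6,12,475,10.7,10,699,16.3,8,572,23.5,7,<0.001
I25,1738,13.0,1201,11.2,10,537,20.3,7,<0.001,72,3.3,15,276,6.2,15,678,15.8,9,712,29.3,5,<0.001
I50,1651,12.4,1163,10.9,13,488,18.5,9,<0.001,83,3.8,14,309,6.9,14,539,12.5,13,720,29.6,4,<0.001
J98,1648,12.3,1239,11.6,9,409,15.5,11,<0.001,197,9.1,10,474,10.6,11,536,12.5,14,441,18.1,12,<0.001
J44,1606,12.0,916,8.5,16,690,26.1,3,<0.001,50,2.3,16,237,5.3,16,559,13.0,10,760,31.2,2,<0.001
M48,1529,11.4,1175,11.0,11,354,13.4,13,<0.001,203,9.3,9,502,11.3,9,552,12.8,11,272,11.2,15,<0.001
I51,1479,11.1,1129,10.5,14,350,13.2,14,<0.001,119,5.5,13,365,8.2,12,546,12.7,12,449,18.5,11,<0.001
E78,1430,10.7,1168,10.9,12,262,9.9,15,0.144,248,11.4,6,529,11.9,8,434,10.1,15,219,9.0,16,0.001
G47,1386,10.4,1020,9.5,15,366,13.9,12,<0.001,155,7.1,11,364,8.2,13,414,9.6,16,453,18.6,10,<0.001
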