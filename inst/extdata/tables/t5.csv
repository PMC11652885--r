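compound_id,ic50_uM,kier_a2,slogp_vsa1,within_svm,low_confidence
II,41.7,4.5847445,7.7454643,TRUE,FALSE
IV,64.5,4.4210858,7.7454643,TRUE,FALSE
4,67.7,5.2678456,7.7454643,TRUE,FALSE
33,NA,4.4425101,5.6876111,FALSE,FALSE
39,59.8,5.5963559,0,TRUE,FALSE
40,NA,3.809427,5.6876111,FALSE,FALSE
42,NA,5.4008284,5.6876111,FALSE,FALSE
43,NA,5.4008284,5.6876111,FALSE,FALSE
53,NA,6.368185,5.6876111,FALSE,FALSE
54,48.9,8.1811314,0,TRUE,FALSE
57,NA,2.9886453,5.6876111,FALSE,FALSE
59,NA,2.0609839,0,FALSE,FALSE
60,66.7,7.5834055,0,TRUE,FALSE
65,NA,3.795996,0,FALSE,FALSE
68,NA,3.8128579,5.6876111,FALSE,FALSE
71,NA,5.9534798,7.7454643,FALSE,FALSE
72,NA,10.287,5.6876111,FALSE,TRUE
77,47,5.4362946,0,TRUE,FALSE
78,NA,16,0,FALSE,FALSE
79,NA,13.104808,0,FALSE,FALSE
81,NA,16.544603,0,FALSE,FALSE
83,25,11.143562,0,TRUE,FALSE
84,NA,12.104386,7.7454643,FALSE,FALSE
85,NA,8.1214361,20.749712,FALSE,FALSE
88,195.7,5.1365461,7.7454643,TRUE,FALSE
89,NA,11.143562,7.7454643,FALSE,FALSE
93,NA,5.4330149,5.2587838,FALSE,FALSE
94,NA,6.0677109,7.7454643,FALSE,FALSE
95,NA,5.9571776,7.7454643,FALSE,FALSE
96,NA,13.066667,0,FALSE,FALSE
98,43.2,3.932668,7.7454643,TRUE,FALSE
99,57,6.7910275,5.6876111,FALSE,FALSE
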