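1.326,0.841,0.282,2.830,0.121
0.644,0.197,1.581,2.178,1.553
1.447,2.343,0.863,3.658,0.132
4.033,3.978,2.416,0.534,0.501
0.458,4.003,0.260,1.099,0.696
0.164,1.271,0.641,3.743,0.395
0.203,0.296,0.529,1.485,2.825
0.115,1.589,2.444,1.219,3.578
0.540,0.507,0.466,0.047,0.334
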