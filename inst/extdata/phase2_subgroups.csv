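5.1,1.2,1.3,0.6,0.5
2.4,0.5,1.1,8.0,0.8
0.4,0.6,0.9,0.4,2.0
0.5,5.3,3.2,2.7,2.9
2.5,2.3,1.0,0.2,0.1
0.1,1.8,0.9,2.0,4.0
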