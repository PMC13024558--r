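case,actual_hy,predicted_hy
1,0,-0.055
2,3,3.093
3,2,1.887
4,0,-0.037
5,2,2.024
6,2,2.158
7,2,2.130
8,3,2.365
9,2,1.669
10,0,0.006
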