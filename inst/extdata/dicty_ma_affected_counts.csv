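affected,observed,expected_sim
0,0,0.01
1,1,0.31
2,4,3.23
3,13,13.59
4,24,28.33
5,34,29.12
6,11,13.38
7,3,2.00
8,0,0.04
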