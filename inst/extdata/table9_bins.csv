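bin,observed_true,observed_false
1,46,6
2,72,8
3,92,12
4,108,15
5,119,26
6,94,68
7,13,78
8,8,52
9,6,32
10,0,19
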