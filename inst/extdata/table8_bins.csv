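bin,observed_true,observed_false
1,34,3
2,63,7
3,88,11
4,105,14
5,123,23
6,95,60
7,9,75
8,6,41
9,4,30
10,0,15
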