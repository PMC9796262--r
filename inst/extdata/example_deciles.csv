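"decile","stria_count"
1,0
2,0
3,3
4,5
5,7
6,9
7,11
8,15
9,19
10,20
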