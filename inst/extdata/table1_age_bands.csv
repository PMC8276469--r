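band,n
4,78
5,119
6,124
7,132
8,142
9,121
10,107
11,90
12,61
13,50
14,42
15,80
16,96
17,92
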