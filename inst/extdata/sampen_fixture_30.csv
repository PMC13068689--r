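value
6
1
8
3
5
9
2
7
4
6
3
8
1
5
7
2
9
4
6
8
3
1
7
5
2
8
6
4
9
3
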