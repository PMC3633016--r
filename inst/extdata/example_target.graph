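#example_target
10
A
B
A
C
B
A
C
A
B
C
11
1 4
2 4
4 6
4 7
0 1
1 5
2 5
5 7
5 8
0 3
0 9
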