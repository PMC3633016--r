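#example_pattern
3
B
A
C
2
0 1
1 2
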