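chromosome	genetic_length_cM
1	186.3
2	226.5
3	168.2
4	169.4
5	118.5
6	165.2
7	132.6
8	131.7
9	134.6
10	112.1
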