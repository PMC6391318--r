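label	n_families
A	10
B	12
C	1
D	8
E	1
F	1
G	11
H	1
I	1
J	1
K	2
L	1
M	1
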