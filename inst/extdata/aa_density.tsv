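aa	heavy_atoms
A	5
R	11
N	8
D	8
C	6
Q	9
E	9
G	4
H	10
I	8
L	8
K	9
M	8
F	11
P	7
S	6
T	7
W	14
Y	12
V	7
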