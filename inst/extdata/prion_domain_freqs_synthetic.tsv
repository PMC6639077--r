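residue	probability
A	0.0466
R	0.0278
N	0.2088
D	0.0292
C	0.0010
Q	0.1671
E	0.0264
G	0.0820
H	0.0197
I	0.0247
L	0.0395
K	0.0306
M	0.0291
F	0.0319
P	0.0510
S	0.0829
T	0.0355
W	0.0062
Y	0.0527
V	0.0308
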