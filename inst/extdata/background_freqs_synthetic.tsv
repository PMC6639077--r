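residue	probability
A	0.0550
R	0.0445
N	0.0614
D	0.0578
C	0.0132
Q	0.0393
E	0.0646
G	0.0498
H	0.0217
I	0.0655
L	0.0957
K	0.0730
M	0.0208
F	0.0449
P	0.0438
S	0.0900
T	0.0589
W	0.0104
Y	0.0337
V	0.0557
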