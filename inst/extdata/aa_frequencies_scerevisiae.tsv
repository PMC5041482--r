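aa	freq
A	0.055
R	0.044
N	0.061
D	0.058
C	0.013
Q	0.039
E	0.064
G	0.05
H	0.022
I	0.066
L	0.096
K	0.073
M	0.021
F	0.045
P	0.044
S	0.09
T	0.059
W	0.01
Y	0.034
V	0.056
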