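aa	w300	dh
A	1.60	-0.9
R	1.25	-0.9
N	0.75	-0.9
D	0.70	-0.9
C	0.90	-0.9
Q	1.00	-0.9
E	0.95	-0.9
G	0.55	-0.9
H	0.85	-0.9
I	1.10	-0.9
L	1.35	-0.9
K	1.15	-0.9
M	1.30	-0.9
F	1.10	-0.9
P	0.10	-0.9
S	0.75	-0.9
T	0.80	-0.9
W	1.55	-0.9
Y	1.05	-0.9
V	0.95	-0.9
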