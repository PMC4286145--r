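code	count
J	164
A	1
K	230
L	188
B	4
D	32
V	33
T	127
M	182
N	64
U	62
O	109
C	215
G	216
E	325
F	76
H	145
I	118
P	171
Q	108
R	391
S	229
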