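# Expected number of residue contacts within 8 Angstrom, per residue.
# Approximate reconstruction of the published contact-based
# amyloidogenicity scale used with the 21.4 threshold; values to 2 dp.
residue,value
A,20.51
R,19.46
N,18.98
D,18.60
C,22.64
Q,19.21
E,18.44
G,19.92
H,20.47
I,23.51
L,22.37
K,18.90
M,22.30
F,23.08
P,17.43
S,19.75
T,20.12
W,22.63
Y,21.41
V,23.40
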