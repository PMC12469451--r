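# Random-coil chemical shifts (ppm) for peptide conformational-shift maps.
# Wishart-style peptide reference values for the 20 canonical residues.
# PTM rows (Cit, hCit, KAc) are the parent residue's values plus small
# corrections; the corrections here are editable placeholders meant to be
# replaced with measured PTM random-coil values when available.
residue	nucleus	shift
A	HA	4.32
R	HA	4.34
N	HA	4.74
D	HA	4.64
C	HA	4.55
Q	HA	4.34
E	HA	4.35
G	HA	3.96
H	HA	4.73
I	HA	4.17
L	HA	4.34
K	HA	4.32
M	HA	4.48
F	HA	4.62
P	HA	4.42
S	HA	4.47
T	HA	4.35
W	HA	4.66
Y	HA	4.55
V	HA	4.12
Cit	HA	4.36
hCit	HA	4.34
KAc	HA	4.35
A	CA	52.5
R	CA	56.0
N	CA	53.1
D	CA	54.2
C	CA	58.2
Q	CA	55.7
E	CA	56.6
G	CA	45.1
H	CA	55.0
I	CA	61.1
L	CA	55.1
K	CA	56.2
M	CA	55.4
F	CA	57.7
P	CA	63.3
S	CA	58.3
T	CA	61.8
W	CA	57.5
Y	CA	57.9
V	CA	62.2
Cit	CA	56.1
hCit	CA	56.4
KAc	CA	56.5
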