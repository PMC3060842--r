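# Amino-acid residue masses in daltons (Da). A residue mass is the mass the
# amino acid contributes inside a peptide chain, i.e. the free amino acid
# minus one water.
# Monoisotopic values computed from IUPAC standard atomic masses
# (C 12.000000, H 1.0078250319, N 14.0030740052, O 15.9949146221,
#  S 31.97207069, Se 79.9165218); average values from IUPAC 2021 standard
# atomic weights.
# standard = 1 for the 20 canonical residues; standard = 0 rows (U =
# selenocysteine, O = pyrrolysine) are only available in permissive mode.
residue	mono	avg	standard
G	57.021464	57.0519	1
A	71.037114	71.0788	1
S	87.032028	87.0782	1
P	97.052764	97.1167	1
V	99.068414	99.1326	1
T	101.047679	101.1051	1
C	103.009185	103.1388	1
L	113.084064	113.1594	1
I	113.084064	113.1594	1
N	114.042927	114.1038	1
D	115.026943	115.0886	1
Q	128.058578	128.1307	1
K	128.094963	128.1741	1
E	129.042593	129.1155	1
M	131.040485	131.1926	1
H	137.058912	137.1411	1
F	147.068414	147.1766	1
R	156.101111	156.1875	1
Y	163.063329	163.1760	1
W	186.079313	186.2132	1
U	150.953636	150.0388	0
O	237.147727	237.3018	0
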