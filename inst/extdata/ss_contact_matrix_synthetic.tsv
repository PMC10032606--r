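# SYNTHETIC side-chain/side-chain contact strengths eps_ss (kcal/mol).
# Constructed from the Kyte-Doolittle hydropathy scale (geometric-mean mixing of
# positive hydropathies, floor 0.05); a synthetic stand-in with the role, units
# and symmetry of a knowledge-based statistical contact matrix.
# version: 1.0-synthetic
residue	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	0.17	0.05	0.05	0.05	0.1914	0.05	0.05	0.05	0.05	0.2397	0.2244	0.05	0.1733	0.1997	0.05	0.05	0.05	0.05	0.05	0.2333
R	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
N	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
D	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
C	0.1914	0.05	0.05	0.05	0.2167	0.05	0.05	0.05	0.05	0.2736	0.2555	0.05	0.1953	0.2264	0.05	0.05	0.05	0.05	0.05	0.266
Q	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
E	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
G	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
H	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
I	0.2397	0.05	0.05	0.05	0.2736	0.05	0.05	0.05	0.05	0.35	0.3257	0.05	0.2449	0.2866	0.05	0.05	0.05	0.05	0.05	0.3398
L	0.2244	0.05	0.05	0.05	0.2555	0.05	0.05	0.05	0.05	0.3257	0.3033	0.05	0.2291	0.2675	0.05	0.05	0.05	0.05	0.05	0.3163
K	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
M	0.1733	0.05	0.05	0.05	0.1953	0.05	0.05	0.05	0.05	0.2449	0.2291	0.05	0.1767	0.2038	0.05	0.05	0.05	0.05	0.05	0.2383
F	0.1997	0.05	0.05	0.05	0.2264	0.05	0.05	0.05	0.05	0.2866	0.2675	0.05	0.2038	0.2367	0.05	0.05	0.05	0.05	0.05	0.2786
P	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
S	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
T	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
W	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
Y	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
V	0.2333	0.05	0.05	0.05	0.266	0.05	0.05	0.05	0.05	0.3398	0.3163	0.05	0.2383	0.2786	0.05	0.05	0.05	0.05	0.05	0.33
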