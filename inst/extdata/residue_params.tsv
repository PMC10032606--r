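# Per-residue side-chain bead parameters for the two-site coarse-grained model.
# sc_sigma: side-chain vdW diameter (Angstrom) from standard residue partial volumes.
# sc_charge: side-chain charge (e) at neutral pH (His neutral).
# bs_bond: backbone-to-side-chain equilibrium bond length (Angstrom).
# version: 1.0
residue	sc_sigma	sc_charge	bs_bond
A	4.004	0	1.53
R	6.092	1	4.1
N	4.833	0	2.5
D	4.75	-1	2.5
C	4.675	0	2.07
Q	5.535	0	3.1
E	5.421	-1	3.1
G	2.673	0	1
H	5.724	0	3.1
I	5.975	0	2.3
L	5.975	0	2.6
K	6.009	1	3.5
M	5.907	0	2.95
F	6.363	0	3.4
P	4.794	0	1.85
S	4.019	0	1.9
T	4.887	0	1.9
W	6.911	0	3.9
Y	6.421	0	3.8
V	5.455	0	2
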