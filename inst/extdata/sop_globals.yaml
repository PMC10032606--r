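# Global energy-function and solvent parameters (units: Angstrom, kcal/mol, ps, e, K)
# version: 1.0
fene_k: 20.0          # FENE bond stiffness, kcal/mol/A^2
fene_R0: 2.0          # FENE maximum bond extension, A
bb_bond: 3.8          # CA(i)-CA(i+1) equilibrium bond length, A
sigma_bb: 3.8         # backbone bead vdW diameter, A
eps_bb: 0.12          # backbone-backbone 12-6 well depth, kcal/mol
eps_bs: 0.18          # backbone-sidechain 12-6 well depth, kcal/mol
eps_exv: 1.0          # local excluded-volume repulsion scale, kcal/mol
sigma_exv: 3.8        # local excluded-volume contact diameter, A
dielectric: 78.5      # relative solvent dielectric
debye_length: 10.0    # Debye screening length, A (physiological monovalent salt)
charged_termini: true # +1e on N-terminal BB bead, -1e on C-terminal BB bead
eta: 1.0e-3           # solvent viscosity, Pa s
a_h: 4.86538          # hydrodynamic bead radius, A (fixes tau_HF = 13.2 ps)
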