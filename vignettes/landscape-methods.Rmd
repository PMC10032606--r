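---
title: "Models and methods: from coarse-grained dynamics to landscape kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from coarse-grained dynamics to landscape kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpscape)
```

## The scientific problem

Short amyloidogenic peptides such as the 40- and 42-residue amyloid-beta
alloforms are intrinsically disordered as monomers: their thermodynamic
ground state is an ensemble of random-coil (RC) structures, and ensemble
averages (radius of gyration, secondary-structure content) look featureless.
Aggregation is nevertheless initiated at the monomer level, by sparsely
populated excitations — the assembly-competent N\* states — that already carry
distance signatures of the fibril polymorphs (the strand-loop-strand U-bend,
the double-hook S-bend).  Because these states live a few kcal/mol above the
RC basin with populations of a few percent, they are invisible to averages
and must be resolved kinetically: by simulating monomer dynamics, partitioning
the trajectories into minima, and measuring barriers, relaxation spectra and
first-passage times between conformational classes.

`idpscape` implements that full chain: a coarse-grained peptide model and
Brownian-dynamics propagator, the fibril-overlap order parameter and DRID
features, kinetic transition networks with min-cut disconnectivity graphs and
roughness profiles, Markov/first-passage kinetics, and restrained two-chain
dimerization summarised as HMM transition networks.  A fixtures module
generates toy references, Markov emitters with closed-form kinetics and
self-avoiding coil ensembles so that every analysis stage can be validated
without any external structure files.

## The energy function

Each residue is represented by two interaction sites: a backbone bead (BB) on
the C-alpha position and a side-chain bead (SC) on the side-chain centroid
(glycine included, with its own small parameters).  The potential decomposes
as

$$U = U_{\mathrm{FENE}} + U_{\mathrm{EXV}} + U_{\mathrm{ELE}} +
      U_{\mathrm{BB}} + U_{\mathrm{BS}} + U_{\mathrm{SS}},$$

with, for bonds, the finite-extensible nonlinear elastic form
$U_{\mathrm{FENE}} = -\tfrac{k R_0^2}{2}\ln[1 - (r - r_0)^2/R_0^2]$
($k = 20$ kcal/mol/Å², $R_0 = 2$ Å), a purely repulsive
$\varepsilon_{\mathrm{exv}}(\sigma_{\mathrm{exv}}/r)^6$ between non-bonded
local pairs (residue separation below 3), screened Debye–Hückel electrostatics
$U_{\mathrm{ELE}} = \frac{k_e q_i q_j}{\epsilon_r r} e^{-r/\lambda_D}$ between
charged side chains and termini (defaults: $\epsilon_r = 78.5$,
$\lambda_D = 10$ Å, physiological monovalent salt), and 12-6 potentials
$\varepsilon[(\sigma/r)^{12} - 2(\sigma/r)^6]$ for all long-range BB–BB,
BB–SC and SC–SC pairs.  The SC–SC well depths carry the sequence specificity
through a statistical contact matrix.

Two data decisions deserve emphasis:

* **All parameters are data, not code.**  The per-residue table (side-chain
  diameters from standard residue volumes, charges, BB–SC bond lengths), the
  contact matrix and the global constants ship as versioned plain-text files
  under `inst/extdata/` and are checksummed into the loaded force field.
* **The shipped contact matrix is synthetic.**  The published
  knowledge-based matrix is not redistributed here; the stand-in
  (`ss_contact_matrix_synthetic.tsv`) is built from a Kyte–Doolittle
  hydropathy scale with geometric-mean mixing, floored at 0.05 kcal/mol and
  capped near 0.35 kcal/mol for the most hydrophobic pair.  It has the right
  role, units, symmetry and magnitude for the pipeline's machinery, but
  quantitative populations computed with it are *not* the calibrated model's.
  Any user with the published table can drop it in the same format.

Local excluded-volume pairs repel at a single contact diameter
$\sigma_{\mathrm{exv}} = 3.8$ Å rather than the mixed bead diameters: bulky
side chains would otherwise stiffen the backbone locally, and the local
geometry is already controlled by the bonded terms.

## Brownian dynamics

The overdamped (high-friction) equation of motion is integrated with the
Ermak–McCammon update.  Free-draining:
$\Delta q = (\Delta t/\gamma)F + \sqrt{2 k_B T \Delta t/\gamma}\,\xi$.  With
hydrodynamic interactions, the drift uses the configuration-dependent
Rotne–Prager–Yamakawa mobility $\mu$ (with the standard overlap-regularised
form below bead contact, which keeps $\mu$ positive definite for every
configuration) and the noise covariance $2 k_B T \mu \Delta t$ is realised
through a dense Cholesky factor — systems here are at most a few hundred
beads, so no Chebyshev approximations are needed.

Units are fixed repo-wide: Ångström, kcal/mol, picoseconds, elementary
charge, Kelvin.  The natural time unit is $\tau_{HF} = \gamma a^2 / E$ with
$a = 1$ Å and $E = 1$ kcal/mol; with water viscosity
$\eta = 10^{-3}$ Pa·s the bead hydrodynamic radius is pinned at
$a_h = 4.86538$ Å so that $\tau_{HF} = 13.2$ ps, and the integration step is
$\Delta t = 0.05\,\tau_{HF}$.  `bd_config()` reports the physical duration of
any run from these constants (a production-scale $8\times10^6$-step
dimerization run spans about 5.3 microseconds).

Two numerical guards stabilise the stiff FENE + soft-core combination at this
step size, and both are inert in thermally relevant regions:

* a step that would carry a bond beyond $0.9 R_0$ (where the Boltzmann weight
  is of order $e^{-100}$ but the FENE force would make the next step
  overshoot) is retried with a halved step and fresh noise, up to 8 times,
  every event counted in the trajectory metadata;
* the deterministic drift displacement of any bead is capped at 0.5 Å per
  step (rescaled with the halved step during retries).  Equilibrium forces
  are an order of magnitude below the cap; only transient deep overlaps —
  which the $(\sigma/r)^6$ excluded volume admits under a rare noise kick —
  trigger it.

The propagator's correctness is tested against statistical mechanics, not
just against itself: single-bead diffusion must satisfy the Einstein
relation, a harmonic bond must carry variance $k_BT/k$ (measured at
$\Delta t = 0.01\,\tau_{HF}$, where the Euler discretisation bias
$2/(2 - k\Delta t/\gamma)$ is below 1%), a double-well potential must
reproduce the analytic stationary density (Kolmogorov–Smirnov check), and
the hydrodynamic propagator must leave stationary averages unchanged while
altering kinetics.

## Order parameters

The fibril-overlap order parameter compares a conformation's backbone
pairwise distances to a reference pair list:
$\chi_{\mathrm{fib}} = \frac{1}{N_p}\sum_j H[d - |r_j - r_j^0|]$, the
fraction of reference pairs reproduced within a tolerance $d$.  A
conformation is classified N\* when $\chi \ge \chi_c = 0.30$ against some
reference (the label of the best-matching qualifying reference wins; ties
break by list order), otherwise RC.  Because the tolerance is not dictated by
theory, it is configuration data: the default $d = 2$ Å is of the order of a
bead radius, and every classification records it.  Pair lists are built from
BB–BB pairs with residue separation at least 3 among the residues resolved in
the reference — close enough to be structure-sensitive, far enough to exclude
trivially bonded pairs.  PDB references are coarse-grained on import
(C-alpha to BB, side-chain heavy-atom centroid to SC) over resolved residues
only.

Discrimination by $\chi$ is a long-chain property: for 12-residue toys a
compact coil frequently reproduces a third of a hairpin's pair distances, and
only from roughly 30 residues upward do coil ensembles fall reliably below
the 0.30 threshold.  The fixture tests therefore validate the RC/N\*
separation at 32 residues and above.

DRID features (distribution of reciprocal interatomic distances) summarise
each conformation by, per centroid (all BB beads), the mean, the square root
of the second central moment and the signed cube root of the third central
moment of reciprocal distances to all non-bonded beads.  The metric is the
Euclidean norm over the concatenated triplets normalised by the component
count.  These features preserve kinetic proximity and are cheap, which is
what the clustering needs.

## From trajectories to a disconnectivity graph

Frames are clustered in DRID space by k-means with multiple restarts under a
fixed seed; the cluster count is selected at the knee (maximum
distance-to-chord) of the dispersion-versus-k curve, with one shortcut: if
some k yields an exactly zero dispersion (planted noiseless states), the
smallest such k wins.  Transition counts $n_{ij}$ at a lag are collected with
a sliding window, never across trajectory boundaries, and symmetrised —
enforcing detailed balance on the network; stationary weights and node free
energies $F_i = -k_BT\ln\pi_i$ follow from the symmetrised counts.

The effective barrier between two node sets is the max-flow/min-cut of the
capacitated network (edge capacity = total transitions both directions,
computed with igraph), converted as
$F^\ddagger = -k_BT \ln(c_{\mathrm{cut}}/N_{\mathrm{total}})$.  The additive
constant of this convention cancels in barrier differences and merge order,
which is all the tree displays.  Pairwise min-cut values inherit the
Gomory–Hu ultrametric property, so the transition disconnectivity graph is
their single-linkage merge tree; merges are floored at the free energies of
the leaves they join (a basin cannot merge below its own minima), and
disconnected components merge last at a flagged sentinel.  Leaves carry the
minimum and maximum member overlap and the fibril-like fraction; the minimum
is the quantity used for colouring (a basin is only as fibril-like as its
least fibril-like member).

The roughness density profile counts, per free-energy bin of width
$\Delta F$, the number of coexisting branches minus one, normalised by the
total number of minima and the bin width, with the per-bin fibril-like
fraction overlaid.  The normalisation is fixed and documented here; it is
defined up to the convention choice, and only profile shapes and comparisons
between systems are meaningful.

## Kinetics

Transition matrices are row-normalised symmetrised counts, so the spectrum is
real (computed through the symmetric similarity transform).  Implied
timescales are $t_i = -\tau/\ln|\lambda_i|$; flatness across lags is the
Markovianity diagnostic.  Duplicate unit eigenvalues (disconnected chains)
report as infinite; zero eigenvalues as instant decay.

Mean first-passage times are computed by graph transformation: iterative
elimination of intermediate nodes with renormalisation of branching
probabilities and waiting times, minimum-degree elimination order (the result
is order-independent; the suite checks it against the linear-system solution
$(I - T_{QQ})m = \tau$ on a thousand random chains).  Empirical
first-passage statistics report the sample mean with a delete-one jackknife
standard error, a single-Gaussian fit to log-times with a KS quality flag
(unimodal log-time distributions indicate two-state kinetics without deep
traps), and a single-exponential KS diagnostic for Poissonian statistics.
Trajectories that never arrive are censored: excluded from the mean, always
reported as a fraction.  Trajectories that start inside the target class are
excluded and counted separately.

## Dimerization

Two chains are propagated with interchain nonbonded parameters identical to
the intrachain ones for the same residue pair, held together by a harmonic
restraint between their centres of mass (default stiffness 5 kcal/mol/Å²) at
a target separation mimicking the critical concentration — a stiff restraint
rather than a rigid constraint, which is simpler and thermodynamically
transparent; the target is computed from the monomer ensemble (the thermally
averaged radius of gyration), not hard-coded.  An interchain contact is any
bead pair on different chains within 6 Å, and a dimer is called when the
count strictly exceeds 5 (6 contacts is a dimer, 5 is not), instantaneously —
no dwell requirement.

Dimer trajectories are featurised as (per-chain overlaps with each
reference, contact count) and discretised with a diagonal-covariance Gaussian
hidden Markov model fitted by Baum–Welch (scaled forward–backward, k-means
initialisation, variance floor $10^{-4}$; the likelihood trace is
non-decreasing and is returned).  The state count is a modelling input — 8
and 16 are the published choices for the two alloforms — and states are
labelled by their emission-mean composition (e.g. `U-RC dimer`).

## Synthetic fixtures and what passing tests do and do not show

The fixtures module generates three reference shapes sharing the two-site
conventions: a two-strand hairpin (U-bend analogue), a three-strand meander
(S-bend analogue) and a fully extended chain.  Multi-strand shapes carry a
±1.3 Å backbone pleat, which contracts intra-strand distances away from the
extended chain by more than the 2 Å tolerance — so the extended template
scores exactly zero against the folded references, and hairpin and meander
score below 0.30 against each other at every length used.

The Markov emitter draws a hidden path from a user transition matrix and
emits frames from per-state templates plus isotropic Gaussian jitter
(default 0.5 Å, small against $d = 2$ Å so classification is unambiguous);
its returned kinetics (stationary weights, the full MFPT matrix) are computed
by exact linear algebra, never by simulation, so they can serve as oracles.
The coil generator samples self-avoiding walks with the pivot algorithm
(bond 3.8 Å, hard core 3.0 Å, seeded, with equilibration and decorrelation
pivot counts scaled with chain length); a confined-walk compact mode provides
collapsed ensembles.

The Flory-exponent check fits $\log\langle R_g\rangle$ against $\log N$ over
chains of 24–128 residues (40 chains each).  The window matters: below ~24
residues the local stiffness of the hard-core chain inflates the apparent
exponent (about 0.64 over 16–96 versus about 0.61 over 24–128, against the
asymptotic self-avoiding-walk value 0.588).  The default window is chosen for
estimator accuracy and reported with the fit.

What the passing tests show: the machinery is internally consistent
(oracle-equivalent where an oracle exists), thermodynamically sound, and
recovers planted structure and kinetics.  What they do not show: quantitative
agreement with the calibrated model's landscape — the synthetic contact
matrix, the desk-scale trajectory lengths (tens of thousands of steps versus
$2\times10^7$ per production trajectory, 100 trajectories per system) and the
synthetic references mean that populations, microsecond MFPTs and the
alloform-specific numbers quoted in the experimental literature are out of
reach here by design.  The qualitative phenomenology is reproduced at desk
scale: trajectories started in fibril-like geometries relax into the
dominant RC state with the fibril-like frames surviving as a minority
(excitations), and template-seeded chain pairs sustain more interchain
contacts than coil-seeded pairs.

## Degenerate inputs and tie-breaks

Empty sequences, unknown residue codes (reported with their position), empty
reference lists, zero-length label streams and non-positive bin widths are
rejected.  All-identical frames cluster to k = 1 with a warning.  Coincident
beads make DRID undefined and are rejected.  Min-cut between disconnected
sets reports an infinite barrier explicitly.  Multi-reference classification
ties break by highest overlap, then list order.  FENE overstretch in a
*user-supplied* conformation is a domain error naming the bond.  The HMM
returns its best model with a warning when EM hits the iteration cap.

## Reproducibility

Every stochastic stage takes an integer seed and records it; identical
config + seed reproduce trajectories bit-for-bit.  Trajectory files
(extended XYZ) carry a JSON sidecar with frame spacing, duration, seed and a
canonical MD5 configuration hash; `run_config()` rejects unknown keys;
`write_manifest()` records inputs, hash, seed and package version for any
stage.  The numbered scripts under `analysis/` run the desk-scale study
end-to-end and write their tables under `results/`.
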