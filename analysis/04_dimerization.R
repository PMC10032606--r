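#!/usr/bin/env Rscript
# Step 4: dimerization kinetics and the HMM substate network.
#
# Pairs of chains are held at a COM separation equal to a coil-scale distance
# (mimicking the critical concentration) and propagated with interchain
# parameters identical to the intrachain ones.  Contact growth is compared
# between template-seeded (both chains in the fibril-like hairpin geometry)
# and coil-seeded starts, and the trajectories are discretised into an HMM
# transition network labelled by chain composition.

suppressPackageStartupMessages(library(idpscape))
seed <- 1L
ff <- load_forcefield()
sq <- strrep("I", 12)
U <- make_toy_reference("hairpin-U", n_res = 12, sequence = sq, ff = ff)
topo <- attr(U, "topology"); tU <- attr(U, "template")
refs <- list(U)

run_one <- function(confA, confB, s) {
  sysd <- setup_dimer(confA, confB, topo, topo, ff, separation = 12,
                      stiffness = 5, seed = s)
  cfg <- bd_config(n_steps = 8000, save_stride = 200, seed = s + 500)
  run_dimerization(sysd, cfg, refs = refs)
}

cat("Running 6 + 6 dimerization trajectories (12-residue chains)...\n")
rc <- make_rc_ensemble(12, 12, seed = 42)
d_nstar <- lapply(1:6, function(s) run_one(tU, tU, s))
d_rc <- lapply(1:6, function(s) run_one(rc[s, , ], rc[s + 6, , ], s))

prof <- data.frame(
  frame = seq_along(d_nstar[[1]]$n_contacts) - 1,
  nstar_seeded = rowMeans(sapply(d_nstar, `[[`, "n_contacts")),
  rc_seeded = rowMeans(sapply(d_rc, `[[`, "n_contacts")))
dir.create("results", showWarnings = FALSE)
write.table(prof, "results/dimer_contact_profiles.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
late <- prof$frame > max(prof$frame) / 2
cat(sprintf("late-window <N_contacts>: template-seeded %.1f, coil-seeded %.1f\n",
            mean(prof$nstar_seeded[late]), mean(prof$rc_seeded[late])))
cat(sprintf("dimer frames (>5 contacts): %d vs %d\n",
            sum(sapply(d_nstar, function(d) sum(d$n_contacts > 5))),
            sum(sapply(d_rc, function(d) sum(d$n_contacts > 5)))))

## HMM transition network over all trajectories
feats <- lapply(c(d_nstar, d_rc), featurize_dimer, refs = refs)
netw <- fit_hmm_network(feats, n_states = 4, ref_labels = "U", seed = seed)
print(netw)
cat("(composition labels are permissive at 12 residues: short coils often\n")
cat(" reach chi >= 0.30 by chance; see the methods vignette)\n")
export_hmm_network(netw, "results/hmm_network")
if (mean(prof$nstar_seeded[late]) > mean(prof$rc_seeded[late])) {
  cat("Finding: template-seeded pairs sustain more interchain contacts than\n")
  cat("coil-seeded pairs -- fibril-like monomers are the better dimer\n")
  cat("templates at this desk scale.\n")
} else {
  cat("Note: no template advantage at this desk scale / seed count;\n")
  cat("production-scale sampling (30 x 8e6 steps) is needed.\n")
}
cat("Network: results/hmm_network/, profile table:\n")
cat("results/dimer_contact_profiles.tsv\n")
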