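#!/usr/bin/env Rscript
# Step 2: the monomer free energy landscape as a TRDG, at desk scale.
#
# Short Brownian-dynamics runs of the 42-residue alloform are started from
# near-fibril (synthetic U-bend/S-bend analogue) and extended conformations,
# clustered in DRID space, and assembled into a transition disconnectivity
# graph whose leaves carry fibril-overlap annotations; the roughness density
# profile is computed from the tree.  Production-scale inputs (100 x 2e7
# steps) would resolve the full landscape; the desk-scale version (4 x 2e4
# steps) demonstrates the machinery and the RC-dominated topography.

suppressPackageStartupMessages(library(idpscape))

seed <- 1L
ff <- load_forcefield()
seq42 <- abeta_sequences[["abeta42"]]
topo <- build_topology(parse_sequence(seq42, "abeta42"), ff)
U <- make_toy_reference("hairpin-U", n_res = 42, sequence = seq42, ff = ff)
S <- make_toy_reference("meander-S", n_res = 42, sequence = seq42, ff = ff)
refs <- list(U, S)

starts <- list(attr(U, "template"), attr(S, "template"),
               extended_conformation(topo), attr(U, "template"))
cat("Running 4 x 20000-step monomer trajectories (42 residues)...\n")
trajs <- lapply(seq_along(starts), function(i) {
  set.seed(seed + i)
  init <- starts[[i]] + matrix(rnorm(length(starts[[i]]), sd = 0.1), ncol = 3)
  cfg <- bd_config(n_steps = 20000, save_stride = 200, seed = seed + i)
  run_trajectory(init, topo, ff, cfg)
})

cm <- cluster_trajectories(trajs, k_range = 1:8, topo = topo, seed = seed)
cat(sprintf("DRID clustering selected k = %d minima\n", cm$k))

net <- count_transitions(cm$labels, lag = 1,
                         lag_ps = trajs[[1]]$dt_save_ps)
ann <- annotate_nodes(trajs, cm$labels, refs, chi_c = 0.30)
tree <- build_trdg(net, annotations = ann)
prof <- roughness_profile(tree, dF = 0.2)

dir.create("results", showWarnings = FALSE)
write.table(cbind(state = seq_len(cm$k), F = net$free_energy, pi = net$pi,
                  ann),
            "results/trdg_minima.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(prof, "results/roughness_profile.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
saveRDS_path <- "results/labels.tsv"
write.table(data.frame(traj = rep(seq_along(cm$labels),
                                  lengths(cm$labels)),
                       label = unlist(cm$labels)),
            saveRDS_path, sep = "\t", row.names = FALSE, quote = FALSE)

g <- which.min(net$free_energy)
cat(sprintf("Ground-state minimum: F = %.2f kcal/mol, fibril fraction %.2f\n",
            net$free_energy[g], ann$frac_fibril[g]))
for (s in seq_len(cm$k))
  cat(sprintf("  minimum %d: F = %.2f kcal/mol, pi = %.2f, chi in [%.2f, %.2f], fibril fraction %.2f\n",
              s, net$free_energy[s], net$pi[s], ann$chi_min[s],
              ann$chi_max[s], ann$frac_fibril[s]))
if (ann$frac_fibril[g] <= min(ann$frac_fibril, na.rm = TRUE) + 1e-9) {
  cat("Finding: the ground-state basin carries the least fibril-like order;\n")
  cat("fibril signatures concentrate in higher-lying minima (N* excitations).\n")
} else {
  cat("Note: at this desk scale the template-seeded starts still dominate\n")
  cat("some low minima; production-scale sampling is needed for converged\n")
  cat("basin populations.\n")
}
cat("Tables: results/trdg_minima.tsv, results/roughness_profile.tsv\n")
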