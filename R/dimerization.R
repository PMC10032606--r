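# Two-chain dimerization: chains held near contact by a stiff harmonic
# restraint between their centres of mass (mimicking the critical protein
# concentration), interchain nonbonded parameters identical to the intrachain
# ones, contact-formation kinetics, and HMM substate transition networks.

#' Assemble a two-chain dimer system
#'
#' Places chain B at a random (seeded) orientation with the two centres of
#' mass separated by `separation`, jittering the orientation until no steric
#' clash remains.  The COM distance is maintained during dynamics by a
#' harmonic restraint of stiffness `stiffness`.
#'
#' @param confA,confB single-chain coordinate matrices.
#' @param topoA,topoB the matching topologies.
#' @param ff force field.
#' @param separation target COM-COM distance in Angstrom (typically the
#'   thermally averaged monomer R_g); must be positive.
#' @param stiffness restraint force constant, kcal/mol/A^2.
#' @param seed RNG seed for the mutual orientation.
#' @param min_dist steric clash threshold in Angstrom.
#' @param max_tries orientation attempts before failing.
#' @return object of class `dimer_system`: merged `topo`, joint `coords`,
#'   `n_A`, `separation`, `stiffness`, precomputed `sys`.
#' @export
setup_dimer <- function(confA, confB, topoA, topoB, ff, separation,
                        stiffness = 5, seed = 1L, min_dist = 2.0,
                        max_tries = 100L) {
  if (separation <= 0) stop("separation must be positive")
  set.seed(seed)
  ctrA <- colMeans(confA)
  A <- sweep(confA, 2, ctrA)
  B0 <- sweep(confB, 2, colMeans(confB))
  for (try in seq_len(max_tries)) {
    R <- .random_rotation()
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    B <- B0 %*% t(R) + matrix(separation * u, nrow(B0), 3, byrow = TRUE)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    if (min(d2) > min_dist^2) {
      topo <- merge_topologies(topoA, topoB)
      coords <- rbind(A, B)
      return(structure(list(topo = topo, coords = coords, n_A = nrow(A),
                            separation = separation, stiffness = stiffness,
                            sys = sop_system(topo, ff)),
                       class = "dimer_system"))
    }
  }
  stop("could not place chains without steric clash after ", max_tries,
       " attempts")
}

# uniform random rotation matrix (quaternion method)
.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# harmonic COM-COM restraint force: U = k/2 (d - d0)^2
.com_restraint_force <- function(coords, nA, d0, k) {
  n <- nrow(coords)
  comA <- colMeans(coords[seq_len(nA), , drop = FALSE])
  comB <- colMeans(coords[(nA + 1):n, , drop = FALSE])
  dv <- comA - comB
  d <- sqrt(sum(dv^2))
  if (d < 1e-9) return(matrix(0, n, 3))
  g <- -k * (d - d0) * dv / d          # force on chain A's COM
  f <- matrix(0, n, 3)
  f[seq_len(nA), ] <- matrix(g / nA, nA, 3, byrow = TRUE)
  f[(nA + 1):n, ] <- matrix(-g / (n - nA), n - nA, 3, byrow = TRUE)
  f
}

#' Run a dimerization simulation
#'
#' Brownian dynamics of the two-chain system with the SOP-IDP forces plus the
#' COM restraint; per saved frame the interchain contact count and (when
#' references are supplied) each chain's N* classification are recorded.
#'
#' @param system a [setup_dimer()] result.
#' @param cfg a [bd_config()].
#' @param refs optional list of [reference_structure()] for per-chain labels
#'   (pair lists must index single-chain beads).
#' @param chi_c overlap threshold.
#' @param cutoff interchain contact cutoff, Angstrom.
#' @return object of class `dimer_trajectory`: `traj` (`sop_trajectory`),
#'   `n_contacts` (per saved frame), `labels_A`, `labels_B`, `n_A`.
#' @export
run_dimerization <- function(system, cfg, refs = NULL, chi_c = 0.30,
                             cutoff = 6) {
  sys <- system$sys
  nA <- system$n_A
  force_fn <- function(x)
    .sop_eval(x, sys, want_forces = TRUE)$forces +
      .com_restraint_force(x, nA, system$separation, system$stiffness)
  traj <- run_trajectory(system$coords, cfg = cfg, force_fn = force_fn,
                         sys = sys)
  fr <- traj$frames
  n <- dim(fr)[2]
  nc <- apply(fr, 1, function(x)
    interchain_contacts(x[seq_len(nA), , drop = FALSE],
                        x[(nA + 1):n, , drop = FALSE],
                        cutoff = cutoff)$n_contacts)
  labA <- labB <- NULL
  if (!is.null(refs)) {
    labA <- apply(fr, 1, function(x)
      as.character(classify_nstar(x[seq_len(nA), , drop = FALSE], refs, chi_c)))
    labB <- apply(fr, 1, function(x)
      as.character(classify_nstar(x[(nA + 1):n, , drop = FALSE], refs, chi_c)))
  }
  structure(list(traj = traj, n_contacts = nc, labels_A = labA,
                 labels_B = labB, n_A = nA),
            class = "dimer_trajectory")
}

#' Featurise a dimer trajectory for HMM fitting
#'
#' Per saved frame: each chain's overlaps with every reference, plus the
#' interchain contact count.
#'
#' @param dtraj a `dimer_trajectory`.
#' @param refs list of [reference_structure()].
#' @return T x (2 * n_refs + 1) feature matrix.
#' @export
featurize_dimer <- function(dtraj, refs) {
  fr <- dtraj$traj$frames
  nA <- dtraj$n_A
  n <- dim(fr)[2]
  t(apply(fr, 1, function(x) {
    a <- vapply(refs, function(r)
      chi_fib(x[seq_len(nA), , drop = FALSE], r), numeric(1))
    b <- vapply(refs, function(r)
      chi_fib(x[(nA + 1):n, , drop = FALSE], r), numeric(1))
    c(a, b, interchain_contacts(x[seq_len(nA), , drop = FALSE],
                                x[(nA + 1):n, , drop = FALSE])$n_contacts)
  }))
}

#' HMM transition network of dimerization substates
#'
#' Fits a diagonal-Gaussian HMM to featurised dimer trajectories and labels
#' each state by its dominant composition (chain classes from the emission
#' means, "dimer" when the mean contact count exceeds 5).
#'
#' @param features list of feature matrices (from [featurize_dimer()]) or a
#'   single matrix.
#' @param n_states number of HMM states (a modelling input; 8 and 16 are the
#'   published choices for the two Abeta alloforms).
#' @param ref_labels labels of the references, in the order used by the
#'   featurisation.
#' @param chi_c threshold applied to emission means for composition labels.
#' @param ... passed to [fit_gaussian_hmm()].
#' @return object of class `hmm_network`: `transmat`, `populations`,
#'   `state_labels`, `means`, `hmm`.
#' @export
fit_hmm_network <- function(features, n_states, ref_labels = NULL,
                            chi_c = 0.30, ...) {
  hmm <- fit_gaussian_hmm(features, n_states, ...)
  A <- hmm$transmat
  # stationary distribution of the fitted chain
  if (n_states == 1L) pops <- 1 else {
    e <- eigen(t(A))
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    pops <- v / sum(v)
  }
  nr <- if (is.null(ref_labels)) (ncol(hmm$means) - 1) / 2 else length(ref_labels)
  lab_of <- function(chis) {
    if (nr == 0 || all(chis < chi_c)) "RC"
    else if (is.null(ref_labels)) paste0("ref", which.max(chis))
    else ref_labels[which.max(chis)]
  }
  state_labels <- apply(hmm$means, 1, function(m) {
    a <- lab_of(m[seq_len(nr)])
    b <- lab_of(m[nr + seq_len(nr)])
    nc <- m[2 * nr + 1]
    paste0(a, "-", b, if (nc > 5) " dimer" else "")
  })
  structure(list(transmat = A, populations = pops,
                 state_labels = state_labels, means = hmm$means, hmm = hmm),
            class = "hmm_network")
}

#' @export
print.hmm_network <- function(x, ...) {
  cat("hmm_network:", nrow(x$transmat), "states\n")
  for (k in seq_len(nrow(x$transmat)))
    cat(sprintf("  %2d %-24s pop %.3f\n", k, x$state_labels[k],
                x$populations[k]))
  invisible(x)
}

#' Export an HMM network as node/edge tables
#'
#' @param netw an `hmm_network`.
#' @param dir output directory; writes `nodes.tsv`, `edges.tsv` and
#'   `network.json`.
#' @return invisibly, the list of file paths.
#' @export
export_hmm_network <- function(netw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(state = seq_along(netw$populations),
                      label = netw$state_labels,
                      population = netw$populations)
  ij <- which(netw$transmat > 1e-6, arr.ind = TRUE)
  edges <- data.frame(from = ij[, 1], to = ij[, 2],
                      probability = netw$transmat[ij])
  fn <- file.path(dir, c("nodes.tsv", "edges.tsv", "network.json"))
  utils::write.table(nodes, fn[1], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(edges, fn[2], sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(nodes = nodes, edges = edges), fn[3],
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(fn)
}
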