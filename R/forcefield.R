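# Two-beads-per-residue SOP-IDP force field: topology construction and the
# decomposed energy/force evaluation
#   U = U_FENE + U_EXV + U_ELE + U_BB + U_BS + U_SS
# Each residue contributes a backbone bead (BB, on the C-alpha position) and a
# side-chain bead (SC, on the side-chain centroid); glycine also carries an SC
# bead with its own (small) parameters.  All parameters are read from plain-text
# tables shipped under inst/extdata and treated strictly as data.

.AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

#' Parse a peptide sequence
#'
#' Accepts a raw one-letter string or a FASTA file path.  Every code must be
#' one of the 20 canonical amino acids.
#'
#' @param x one-letter sequence string, character vector of codes, or the path
#'   to a FASTA file (first record used).
#' @param id optional label; defaults to the FASTA header or `"seq"`.
#' @return object of class `sop_sequence` with fields `residues` and `id`.
#' @export
parse_sequence <- function(x, id = NULL) {
  if (length(x) == 1L && file.exists(x) && !grepl("^[ARNDCQEGHILKMFPSTWYV]+$", x)) {
    fa <- seqinr::read.fasta(x, seqtype = "AA", as.string = FALSE)
    if (length(fa) == 0L) stop("no sequences in FASTA file: ", x)
    res <- toupper(as.character(fa[[1]]))
    if (is.null(id)) id <- attr(fa[[1]], "name")
  } else {
    res <- if (length(x) == 1L) strsplit(toupper(x), "")[[1]] else toupper(x)
  }
  if (length(res) == 0L) stop("empty sequence")
  bad <- which(!res %in% .AA1)
  if (length(bad) > 0L)
    stop("unknown residue code '", res[bad[1]], "' at position ", bad[1])
  structure(list(residues = res, id = if (is.null(id)) "seq" else id),
            class = "sop_sequence")
}

#' Load the SOP-IDP force field from parameter tables
#'
#' Reads the per-residue table, the side-chain contact matrix and the global
#' parameter document from a directory of versioned plain-text files (defaults
#' to the tables shipped with the package; the contact matrix shipped here is a
#' synthetic hydropathy-derived stand-in, see its header).  File checksums are
#' recorded in the returned object so any run can state exactly which tables it
#' used.
#'
#' @param dir directory holding `residue_params.tsv`,
#'   `ss_contact_matrix_synthetic.tsv` and `sop_globals.yaml`.
#' @return object of class `sop_forcefield`.
#' @export
load_forcefield <- function(dir = system.file("extdata", package = "idpscape")) {
  fres <- file.path(dir, "residue_params.tsv")
  fmat <- file.path(dir, "ss_contact_matrix_synthetic.tsv")
  fglob <- file.path(dir, "sop_globals.yaml")
  for (f in c(fres, fmat, fglob))
    if (!file.exists(f)) stop("missing parameter file: ", f)
  res <- utils::read.delim(fres, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "sc_sigma", "sc_charge", "bs_bond") %in% names(res)),
            setequal(res$residue, .AA1), all(res$sc_sigma > 0))
  rownames(res) <- res$residue
  mat <- utils::read.delim(fmat, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  eps_ss <- as.matrix(mat[, -1]); rownames(eps_ss) <- mat$residue
  eps_ss <- eps_ss[.AA1, .AA1]
  if (max(abs(eps_ss - t(eps_ss))) > 1e-12)
    stop("side-chain contact matrix is not symmetric")
  if (any(eps_ss < 0)) stop("negative eps_ss entries")
  glob <- yaml::read_yaml(fglob)
  need <- c("fene_k", "fene_R0", "bb_bond", "sigma_bb", "eps_bb", "eps_bs",
            "eps_exv", "sigma_exv", "dielectric", "debye_length",
            "charged_termini", "eta", "a_h")
  miss <- setdiff(need, names(glob))
  if (length(miss) > 0L) stop("missing globals: ", paste(miss, collapse = ", "))
  stopifnot(glob$fene_R0 > 0, glob$sigma_bb > 0, glob$eps_bb >= 0)
  structure(list(residues = res, eps_ss = eps_ss, globals = glob,
                 checksums = tools::md5sum(c(fres, fmat, fglob))),
            class = "sop_forcefield")
}

#' Build a two-site topology from a sequence
#'
#' Beads are interleaved: residue `i` owns BB bead `2i - 1` and SC bead `2i`.
#' Bonds are BB(i)-BB(i+1) along the backbone and BB(i)-SC(i) within each
#' residue.  Charges sit on the side chains of D/E/K/R; the termini optionally
#' carry +1e (N) and -1e (C) on their backbone beads.
#'
#' @param seq an `sop_sequence` (or string accepted by [parse_sequence()]).
#' @param ff an `sop_forcefield`.
#' @param chain integer chain id stored with every bead.
#' @return object of class `sop_topology` with data frames `beads` and `bonds`.
#' @export
build_topology <- function(seq, ff, chain = 1L) {
  if (!inherits(seq, "sop_sequence")) seq <- parse_sequence(seq)
  g <- ff$globals
  n <- length(seq$residues)
  aa <- seq$residues
  sc <- ff$residues[aa, ]
  beads <- data.frame(
    index = seq_len(2L * n),
    res = rep(seq_len(n), each = 2L),
    site = rep(c("BB", "SC"), n),
    aa = rep(aa, each = 2L),
    charge = as.vector(rbind(0, sc$sc_charge)),
    sigma = as.vector(rbind(g$sigma_bb, sc$sc_sigma)),
    chain = chain,
    stringsAsFactors = FALSE)
  if (isTRUE(g$charged_termini)) {
    beads$charge[1L] <- beads$charge[1L] + 1
    beads$charge[2L * n - 1L] <- beads$charge[2L * n - 1L] - 1
  }
  bb <- 2L * seq_len(n) - 1L
  bonds <- rbind(
    if (n > 1L) data.frame(i = bb[-n], j = bb[-1], r0 = g$bb_bond),
    data.frame(i = bb, j = bb + 1L, r0 = sc$bs_bond))
  structure(list(beads = beads, bonds = bonds, n_res = n, id = seq$id,
                 chain = chain),
            class = "sop_topology")
}

#' @export
print.sop_topology <- function(x, ...) {
  cat("sop_topology:", x$id, "-", x$n_res, "residues,", nrow(x$beads),
      "beads,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Backbone bead indices of a topology
#' @param topo an `sop_topology`.
#' @return integer vector of BB bead indices.
#' @export
bb_indices <- function(topo) topo$beads$index[topo$beads$site == "BB"]

# Merge two topologies into one two-chain system; bead indices of the second
# chain are shifted, residue separation across chains is infinite (all
# interchain nonbonded pairs use the long-range 12-6 classes with parameters
# identical to the intrachain ones for the same residue pair).
#' Merge two chain topologies into a two-chain system
#' @param topoA,topoB `sop_topology` objects.
#' @return combined `sop_topology` with distinct `chain` ids.
#' @export
merge_topologies <- function(topoA, topoB) {
  off <- nrow(topoA$beads)
  bB <- topoB$beads
  bB$index <- bB$index + off
  bB$chain <- topoA$beads$chain[1] + 1L
  bonds <- rbind(topoA$bonds,
                 data.frame(i = topoB$bonds$i + off, j = topoB$bonds$j + off,
                            r0 = topoB$bonds$r0))
  structure(list(beads = rbind(topoA$beads, bB), bonds = bonds,
                 n_res = topoA$n_res + topoB$n_res,
                 id = paste0(topoA$id, "+", topoB$id),
                 chain = c(topoA$chain, bB$chain[1]),
                 n_beads_A = off),
            class = "sop_topology")
}

# Precompute the nonbonded pair table.  Pair classes:
#   EXV - non-bonded pairs with residue separation < 3 on the same chain
#         (purely repulsive (sigma/r)^6)
#   BB/BS/SS - all other pairs, 12-6 potential eps[(s/r)^12 - 2(s/r)^6]
# Screened-Coulomb electrostatics act additively on every non-bonded pair with
# a nonzero charge product.
#' Precompute the interaction system for fast repeated evaluation
#' @param topo an `sop_topology`.
#' @param ff an `sop_forcefield`.
#' @return object of class `sop_system` used by [sop_energy()] and the
#'   dynamics engine.
#' @export
sop_system <- function(topo, ff) {
  b <- topo$beads
  n <- nrow(b)
  g <- ff$globals
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(topo$bonds$i, topo$bonds$j)] <- TRUE
  keep <- !bonded[cbind(i, j)]
  i <- i[keep]; j <- j[keep]
  same_chain <- b$chain[i] == b$chain[j]
  sep <- ifelse(same_chain, abs(b$res[i] - b$res[j]), Inf)
  site_i <- b$site[i]; site_j <- b$site[j]
  cls <- ifelse(sep < 3, "EXV",
         ifelse(site_i == "BB" & site_j == "BB", "BB",
         ifelse(site_i == "SC" & site_j == "SC", "SS", "BS")))
  eps <- numeric(length(i))
  eps[cls == "EXV"] <- g$eps_exv
  eps[cls == "BB"] <- g$eps_bb
  eps[cls == "BS"] <- g$eps_bs
  ss <- cls == "SS"
  eps[ss] <- ff$eps_ss[cbind(b$aa[i[ss]], b$aa[j[ss]])]
  # local pairs repel at a single contact diameter (keeps the chain locally
  # flexible); long-range 12-6 pairs mix bead diameters arithmetically
  sigma <- ifelse(cls == "EXV", g$sigma_exv, (b$sigma[i] + b$sigma[j]) / 2)
  pairs <- data.frame(i = i, j = j, cls = cls, sigma = sigma, eps = eps,
                      qq = b$charge[i] * b$charge[j])
  structure(list(topo = topo, pairs = pairs, bonds = topo$bonds,
                 fene_k = g$fene_k, fene_R0 = g$fene_R0,
                 ke = .KE_COULOMB / g$dielectric, debye = g$debye_length,
                 n_beads = n),
            class = "sop_system")
}

# Single evaluation core: energy breakdown and (optionally) forces = -grad U.
.sop_eval <- function(coords, sys, want_forces = FALSE) {
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) != sys$n_beads)
    stop("conformation must be an n_beads x 3 coordinate matrix")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  p <- sys$pairs
  n <- sys$n_beads
  f <- if (want_forces) matrix(0, n, 3) else NULL

  acc <- function(f, ii, jj, dudr, dx, r) {
    fp <- -(dudr / r) * dx            # force on i; -fp acts on j
    a <- rowsum(rbind(fp, -fp), group = c(ii, jj))
    at <- as.integer(rownames(a))
    f[at, ] <- f[at, ] + a
    f
  }

  # FENE bonds
  bi <- sys$bonds$i; bj <- sys$bonds$j
  dxb <- coords[bi, , drop = FALSE] - coords[bj, , drop = FALSE]
  rb <- sqrt(rowSums(dxb^2))
  dev <- rb - sys$bonds$r0
  over <- abs(dev) >= sys$fene_R0
  if (any(over)) {
    k <- which(over)[1]
    stop(sprintf("FENE bond %d-%d overstretched (|r - r0| = %.3f A >= R0 = %.3f A)",
                 bi[k], bj[k], abs(dev[k]), sys$fene_R0), call. = FALSE)
  }
  x2 <- (dev / sys$fene_R0)^2
  e_fene <- sum(-0.5 * sys$fene_k * sys$fene_R0^2 * log1p(-x2))
  if (want_forces)
    f <- acc(f, bi, bj, sys$fene_k * dev / (1 - x2), dxb, rb)

  dx <- coords[p$i, , drop = FALSE] - coords[p$j, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  if (any(r < 1e-9)) stop("coincident beads in nonbonded pair")
  comp <- c(FENE = e_fene, EXV = 0, ELE = 0, BB = 0, BS = 0, SS = 0)

  ex <- p$cls == "EXV"
  if (any(ex)) {
    sr6 <- (p$sigma[ex] / r[ex])^6
    e <- p$eps[ex] * sr6
    comp["EXV"] <- sum(e)
    if (want_forces)
      f <- acc(f, p$i[ex], p$j[ex], -6 * e / r[ex],
               dx[ex, , drop = FALSE], r[ex])
  }
  for (cl in c("BB", "BS", "SS")) {
    s <- p$cls == cl
    if (!any(s)) next
    sr6 <- (p$sigma[s] / r[s])^6
    comp[cl] <- sum(p$eps[s] * (sr6^2 - 2 * sr6))
    if (want_forces)
      f <- acc(f, p$i[s], p$j[s], -12 * p$eps[s] * (sr6^2 - sr6) / r[s],
               dx[s, , drop = FALSE], r[s])
  }
  q <- p$qq != 0
  if (any(q)) {
    e <- sys$ke * p$qq[q] * exp(-r[q] / sys$debye) / r[q]
    comp["ELE"] <- sum(e)
    if (want_forces)
      f <- acc(f, p$i[q], p$j[q], -e * (1 / r[q] + 1 / sys$debye),
               dx[q, , drop = FALSE], r[q])
  }
  list(components = comp, total = sum(comp), forces = f)
}

#' Decomposed SOP-IDP energy
#'
#' @param conf n_beads x 3 coordinate matrix (Angstrom).
#' @param topo an `sop_topology` (ignored if `sys` given).
#' @param ff an `sop_forcefield` (ignored if `sys` given).
#' @param sys optional precomputed [sop_system()] for repeated calls.
#' @return list with `components` (named FENE/EXV/ELE/BB/BS/SS, kcal/mol) and
#'   `total`.
#' @export
sop_energy <- function(conf, topo = NULL, ff = NULL, sys = NULL) {
  if (is.null(sys)) sys <- sop_system(topo, ff)
  out <- .sop_eval(conf, sys, want_forces = FALSE)
  out[c("components", "total")]
}

#' SOP-IDP forces
#'
#' @inheritParams sop_energy
#' @return n_beads x 3 matrix of forces (-grad U, kcal/mol/Angstrom).
#' @export
sop_forces <- function(conf, topo = NULL, ff = NULL, sys = NULL) {
  if (is.null(sys)) sys <- sop_system(topo, ff)
  .sop_eval(conf, sys, want_forces = TRUE)$forces
}

#' Straight-chain starting conformation
#'
#' Extended backbone along x with side chains alternating above/below the
#' backbone; a convenient, overlap-free initial condition for dynamics.
#'
#' @param topo an `sop_topology` (single chain).
#' @return coordinate matrix.
#' @export
extended_conformation <- function(topo) {
  n <- topo$n_res
  g <- 3.8
  coords <- matrix(0, nrow(topo$beads), 3)
  bb <- bb_indices(topo)
  coords[bb, 1] <- g * (seq_len(n) - 1)
  bs <- topo$bonds[topo$bonds$j %in% (bb + 1L), ]
  side <- rep_len(c(1, -1), n)
  coords[bb + 1L, ] <- coords[bb, ] +
    cbind(0, 0, side * bs$r0[match(bb, bs$i)])
  coords
}
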