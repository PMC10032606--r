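# Synthetic fixtures: deterministic toy fibril references (hairpin-U,
# meander-S, extended), Markov-chain trajectory emitters with closed-form
# kinetics, and self-avoiding random-coil ensembles with good-solvent
# statistics.  Every ground-truth quantity is computed analytically (linear
# algebra), never by simulation.  Geometries use the same two-beads-per-
# residue conventions as the real model so all order-parameter code paths are
# exercised unchanged.

# strand layout: residues laid on n_strands antiparallel strands 4.8 A apart
# (cross-strand register as in a beta sheet).  Multi-strand shapes carry a
# strong pleat (z alternating +-1.3 A, bond length kept at 3.8 A) so their
# intra-strand distances contract away from the fully extended chain by more
# than the default 2 A overlap tolerance; the 1-strand "extended" shape is a
# straight line.  SC beads sit above the local backbone position at their
# per-residue bond length so the template is a valid conformation of the
# attached topology.
.strand_coords <- function(n_res, n_strands, sc_len = rep(2.8, n_res)) {
  per <- ceiling(n_res / n_strands)
  pleat <- if (n_strands > 1) 1.3 else 0
  dx <- sqrt(3.8^2 - (2 * pleat)^2)
  bb <- matrix(0, n_res, 3)
  x <- 0; y <- 0; dir <- 1; ph <- 1
  for (i in seq_len(n_res)) {
    bb[i, ] <- c(x, y, pleat * ph)
    if (i %% per == 0 && i < n_res) {   # turn: step up, reverse direction;
      y <- y + 4.8                      # pleat phase held so the turn bond
      dir <- -dir                       # stays near its rest length
    } else {
      x <- x + dir * dx
      ph <- -ph
    }
  }
  coords <- matrix(0, 2 * n_res, 3)
  coords[2 * seq_len(n_res) - 1, ] <- bb
  coords[2 * seq_len(n_res), ] <- bb + cbind(0, 0, sc_len)
  coords
}

#' Deterministic toy fibril-monomer references
#'
#' Three rigid bead geometries sharing the two-site chain conventions: a
#' two-strand hairpin (`"hairpin-U"`, the strand-loop-strand U-bend
#' analogue), a three-strand meander (`"meander-S"`, the S-bend analogue) and
#' a fully `"extended"` chain.  Hairpin and meander are mutually
#' distinguishable under the default overlap tolerance (cross overlaps fall
#' below the 0.30 threshold) and the extended chain matches neither.
#'
#' @param shape one of `"hairpin-U"`, `"meander-S"`, `"extended"`.
#' @param n_res residue count (default 12).
#' @param d overlap tolerance in Angstrom.
#' @param sequence optional sequence for the attached topology (default:
#'   poly-A of length `n_res`).
#' @param ff force field used to build the attached topology (default:
#'   shipped tables).
#' @return a [reference_structure()] with attributes `template` (the
#'   coordinates) and `topology`.
#' @export
make_toy_reference <- function(shape = c("hairpin-U", "meander-S", "extended"),
                               n_res = 12L, d = 2,
                               sequence = strrep("A", n_res), ff = NULL) {
  shape <- match.arg(shape)
  if (is.null(ff)) ff <- load_forcefield()
  n_strands <- switch(shape, "hairpin-U" = 2L, "meander-S" = 3L,
                      "extended" = 1L)
  topo <- build_topology(parse_sequence(sequence, id = shape), ff)
  coords <- .strand_coords(n_res, n_strands,
                           sc_len = ff$residues[topo$beads$aa[
                             topo$beads$site == "SC"], "bs_bond"])
  ref <- reference_structure(coords = coords, topo = topo, d = d,
                             label = shape)
  attr(ref, "template") <- coords
  attr(ref, "topology") <- topo
  ref
}

#' Toy Markov-chain trajectory with known kinetics
#'
#' Samples a hidden-state path from a discrete-time chain and emits bead
#' frames from per-state geometric templates plus isotropic Gaussian jitter.
#' The returned ground truth (stationary distribution, MFPT matrix in frames)
#' is computed by exact linear algebra from the chain, never by simulation.
#'
#' @param trans row-stochastic transition matrix (per frame).
#' @param templates list of bead coordinate matrices, one per state (equal
#'   dimensions).
#' @param n_frames trajectory length in frames.
#' @param jitter isotropic Gaussian emission noise, Angstrom (default 0.5,
#'   small against the 2 Angstrom overlap tolerance).
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @param start initial state (default: sampled from the stationary
#'   distribution).
#' @return list with `labels` (hidden path), `frames` (array), `trans`,
#'   `stationary`, `mfpt` (matrix, `mfpt[i, j]` = expected frames from i to
#'   j).
#' @export
simulate_toy_markov <- function(trans, templates, n_frames, jitter = 0.5,
                                seed = 1L, start = NULL) {
  trans <- as.matrix(trans)
  K <- nrow(trans)
  stopifnot(K == length(templates), all(trans >= 0),
            max(abs(rowSums(trans) - 1)) < 1e-10, n_frames >= 1)
  e <- eigen(t(trans))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  stationary <- v / sum(v)
  mfpt <- matrix(0, K, K)
  for (j in seq_len(K)) {
    Q <- trans[-j, -j, drop = FALSE]
    m <- solve(diag(K - 1) - Q, rep(1, K - 1))
    mfpt[-j, j] <- m
  }
  set.seed(seed)
  labels <- integer(n_frames)
  labels[1] <- if (is.null(start)) sample.int(K, 1, prob = stationary)
               else as.integer(start)
  for (t in seq_len(n_frames - 1))
    labels[t + 1] <- sample.int(K, 1, prob = trans[labels[t], ])
  nb <- nrow(templates[[1]])
  frames <- array(0, c(n_frames, nb, 3))
  for (t in seq_len(n_frames))
    frames[t, , ] <- templates[[labels[t]]] +
      matrix(stats::rnorm(3 * nb, sd = jitter), nb, 3)
  list(labels = labels, frames = frames, trans = trans,
       stationary = stationary, mfpt = mfpt)
}

# one pivot move on a backbone chain; returns NULL on rejection
.pivot_once <- function(bb, excl2) {
  n <- nrow(bb)
  p <- sample(2:(n - 1), 1)
  R <- .random_rotation()
  tail <- (p + 1):n
  newtail <- sweep(sweep(bb[tail, , drop = FALSE], 2, bb[p, ]) %*% t(R),
                   2, bb[p, ], "+")
  head <- bb[1:p, , drop = FALSE]
  d2 <- outer(rowSums(head^2), rowSums(newtail^2), "+") -
    2 * tcrossprod(head, newtail)
  # exclude the bonded neighbour p -> p+1
  d2[p, 1] <- Inf
  if (min(d2) < excl2) return(NULL)
  d2t <- outer(rowSums(newtail^2), rowSums(newtail^2), "+") -
    2 * tcrossprod(newtail)
  diag(d2t) <- Inf
  nt <- length(tail)
  if (nt > 1) {
    d2t[cbind(1:(nt - 1), 2:nt)] <- Inf
    d2t[cbind(2:nt, 1:(nt - 1))] <- Inf
    if (min(d2t) < excl2) return(NULL)
  }
  bb[tail, ] <- newtail
  bb
}

#' Self-avoiding random-coil ensemble
#'
#' Backbone chains sampled with the pivot algorithm (good-solvent mode:
#' uniform self-avoiding walks with bond length 3.8 Angstrom and a hard-core
#' bead diameter), or compact chains from a sphere-confined random walk.
#' Side-chain beads are attached at a fixed offset so frames carry the full
#' two-site bead count.
#'
#' @param n_res residues per chain (>= 5).
#' @param n_frames number of independent-ish chains (pivot-decorrelated).
#' @param seed RNG seed.
#' @param mode `"good"` (self-avoiding, Flory exponent about 0.6) or
#'   `"compact"` (confined walk, collapsed statistics).
#' @param excluded_diameter hard-core bead diameter, Angstrom.
#' @param equil_pivots accepted pivots before the first frame.
#' @param decorr_pivots accepted pivots between frames.
#' @param sc_len per-residue backbone-to-side-chain offsets, Angstrom; pass
#'   the topology's bond lengths when the frames will seed dynamics.
#' @return frames array (n_frames x 2 n_res x 3).
#' @export
make_rc_ensemble <- function(n_res, n_frames, seed = 1L,
                             mode = c("good", "compact"),
                             excluded_diameter = 3.0,
                             equil_pivots = 20L * n_res,
                             decorr_pivots = 3L * n_res,
                             sc_len = rep(2.8, n_res)) {
  mode <- match.arg(mode)
  stopifnot(n_res >= 5, length(sc_len) == n_res)
  set.seed(seed)
  frames <- array(0, c(n_frames, 2L * n_res, 3L))
  put <- function(t, bb) {
    frames[t, 2 * seq_len(n_res) - 1, ] <<- bb
    frames[t, 2 * seq_len(n_res), ] <<- bb + cbind(0, 0, sc_len)
  }
  if (mode == "compact") {
    rmax <- 2.2 * n_res^(1 / 3) * 3.8 / 2
    for (t in seq_len(n_frames)) {
      bb <- matrix(0, n_res, 3)
      for (i in 2:n_res) {
        repeat {
          u <- stats::rnorm(3); u <- 3.8 * u / sqrt(sum(u^2))
          cand <- bb[i - 1, ] + u
          if (sum(cand^2) < rmax^2) break
        }
        bb[i, ] <- cand
      }
      put(t, bb)
    }
    return(frames)
  }
  excl2 <- excluded_diameter^2
  bb <- cbind(3.8 * (seq_len(n_res) - 1), 0, 0)
  advance <- function(bb, n_acc) {
    acc <- 0L
    while (acc < n_acc) {
      cand <- .pivot_once(bb, excl2)
      if (!is.null(cand)) { bb <- cand; acc <- acc + 1L }
    }
    bb
  }
  bb <- advance(bb, equil_pivots)
  for (t in seq_len(n_frames)) {
    put(t, bb)
    if (t < n_frames) bb <- advance(bb, decorr_pivots)
  }
  frames
}

#' Flory scaling exponent of the random-coil generator
#'
#' Generates good-solvent ensembles at several chain lengths, averages the
#' backbone radius of gyration per length, and fits `log <Rg> ~ nu log N`.
#' The default length window starts at 24 residues: shorter chains carry a
#' local-stiffness finite-size bias that inflates the apparent exponent.
#'
#' @param lengths residue counts to simulate.
#' @param n_frames chains per length.
#' @param seed RNG seed.
#' @param mode passed to [make_rc_ensemble()].
#' @return list with `nu` (fitted exponent), `rg` (mean Rg per length),
#'   `lengths`, `fit` (the `lm` object).
#' @export
flory_exponent <- function(lengths = c(24, 32, 48, 64, 96, 128), n_frames = 40,
                           seed = 1L, mode = "good") {
  rg <- vapply(seq_along(lengths), function(k) {
    n <- lengths[k]
    fr <- make_rc_ensemble(n, n_frames, seed = seed + k, mode = mode)
    bbi <- 2 * seq_len(n) - 1
    mean(apply(fr, 1, function(x) radius_of_gyration(x[bbi, , drop = FALSE])))
  }, numeric(1))
  fit <- stats::lm(log(rg) ~ log(lengths))
  list(nu = unname(stats::coef(fit)[2]), rg = rg, lengths = lengths,
       fit = fit)
}
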