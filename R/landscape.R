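# From trajectories to a kinetic transition network and its transition
# disconnectivity graph (TRDG): DRID-space clustering with knee-point model
# selection, lag-time transition counting, min-cut (max-flow) barriers, the
# ultrametric merge tree, and the Levy-Becker-style roughness density profile.

#' Knee point of a monotone curve
#'
#' Index of maximum perpendicular distance to the chord joining the curve's
#' endpoints (a standard elbow criterion).
#'
#' @param x,y curve coordinates (equal length, `x` increasing).
#' @return index of the knee.
#' @export
knee_point <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  num <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1)
  which.max(num / sqrt((y2 - y1)^2 + (x2 - x1)^2))
}

#' Cluster trajectories in DRID space
#'
#' Centroid-based (k-means) partition of all frames in DRID feature space for
#' each candidate cluster count; the reported model is the knee of the
#' within-cluster dispersion curve.  Multiple restarts with a fixed seed make
#' the selection deterministic.
#'
#' @param trajs list of trajectories (`sop_trajectory`/frame arrays, converted
#'   with `topo`) or list of precomputed feature matrices.
#' @param k_range candidate cluster counts.
#' @param topo topology (needed when `trajs` are trajectories).
#' @param seed RNG seed.
#' @param nstart k-means restarts per k.
#' @return object of class `cluster_model`: `k`, `centers`, `labels` (list,
#'   one integer vector per trajectory), `dispersion` (per k), `k_range`.
#' @export
cluster_trajectories <- function(trajs, k_range = 1:8, topo = NULL, seed = 1L,
                                 nstart = 5L) {
  if (!is.list(trajs) || inherits(trajs, "sop_trajectory")) trajs <- list(trajs)
  feats <- lapply(trajs, function(tr)
    if (is.matrix(tr)) tr else drid_features(tr, topo))
  X <- do.call(rbind, feats)
  lens <- vapply(feats, nrow, integer(1))
  if (nrow(X) < 2L) stop("need at least 2 frames")
  k_range <- sort(unique(pmin(k_range, nrow(X))))
  if (nrow(unique(X)) == 1L) {
    warning("all frames identical; k = 1")
    labels <- split(rep(1L, nrow(X)), rep(seq_along(lens), lens))
    return(structure(list(k = 1L, centers = X[1, , drop = FALSE],
                          labels = unname(labels), dispersion = 0,
                          k_range = 1L), class = "cluster_model"))
  }
  k_range <- k_range[k_range <= nrow(unique(X))]
  set.seed(seed)
  fits <- lapply(k_range, function(k) {
    if (k == 1L) {
      ctr <- colMeans(X)
      list(cluster = rep(1L, nrow(X)), centers = matrix(ctr, 1),
           tot.withinss = sum(sweep(X, 2, ctr)^2))
    } else {
      stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50)
    }
  })
  disp <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  zero <- which(disp <= max(disp) * 1e-12)
  kk <- if (length(zero) > 0L) zero[1]            # exact partition exists
        else if (length(k_range) == 1L) 1L
        else knee_point(k_range, disp)
  best <- fits[[kk]]
  labels <- split(best$cluster, rep(seq_along(lens), lens))
  structure(list(k = k_range[kk], centers = best$centers,
                 labels = unname(lapply(labels, as.integer)),
                 dispersion = disp, k_range = k_range),
            class = "cluster_model")
}

#' Count lag-time transitions and build the transition network
#'
#' Sliding-window counts `n_ij` of observed `i -> j` hops at lag `lag`
#' (frames), never across trajectory boundaries.  Stationary weights come from
#' the symmetrised counts, and node free energies are `F_i = -kBT log pi_i`.
#'
#' @param labels integer label vector, or list of vectors (one per
#'   trajectory).
#' @param lag lag in frames (>= 1).
#' @param temperature temperature in K used for the free-energy scale.
#' @param n_states number of states (default: max label).
#' @param lag_ps optional physical lag time in ps, stored for unit-carrying
#'   downstream analyses.
#' @return object of class `transition_network`: `counts` (raw), `sym`
#'   (symmetrised), `pi`, `free_energy` (kcal/mol), `lag`, `lag_ps`, `kBT`,
#'   `n_total`.
#' @export
count_transitions <- function(labels, lag = 1L, temperature = 298,
                              n_states = NULL, lag_ps = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  labels <- lapply(labels, as.integer)
  if (sum(lengths(labels)) == 0L) stop("empty labels")
  stopifnot(lag >= 1)
  if (is.null(n_states)) n_states <- max(unlist(labels))
  C <- matrix(0, n_states, n_states)
  for (lab in labels) {
    if (length(lab) <= lag) next
    from <- lab[seq_len(length(lab) - lag)]
    to <- lab[(lag + 1):length(lab)]
    tab <- table(factor(from, levels = 1:n_states),
                 factor(to, levels = 1:n_states))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  sym <- (C + t(C)) / 2
  pi <- rowSums(sym) / sum(sym)
  kBT <- thermal_energy(temperature)
  structure(list(counts = C, sym = sym, pi = pi,
                 free_energy = -kBT * log(pi), lag = lag, lag_ps = lag_ps,
                 kBT = kBT, n_total = sum(C)),
            class = "transition_network")
}

# igraph over the symmetrised counts; undirected edge capacity
# c_ij = n_ij + n_ji (total observed traffic over the edge).
.net_graph <- function(net) {
  cap <- 2 * net$sym
  diag(cap) <- 0
  igraph::graph_from_adjacency_matrix(cap, mode = "undirected",
                                      weighted = TRUE)
}

#' Min-cut barrier between two node sets
#'
#' Max-flow/min-cut over the capacitated transition network (capacities are
#' the total transition counts per edge); the effective free-energy barrier is
#' `F = -kBT log(c_cut / n_total)`.  The constant offset from this convention
#' cancels in barrier differences and merge order.
#'
#' @param net a `transition_network`.
#' @param A,B disjoint non-empty node index sets.
#' @return list with `barrier` (kcal/mol; `Inf` if disconnected), `cut_value`
#'   and the partition (`cut_A` side node set).
#' @export
mincut_barrier <- function(net, A, B) {
  A <- unique(as.integer(A)); B <- unique(as.integer(B))
  n <- nrow(net$sym)
  stopifnot(length(A) > 0, length(B) > 0, length(intersect(A, B)) == 0,
            max(A, B) <= n)
  g <- .net_graph(net)
  big <- sum(net$sym) * 4 + 1
  # super-source/sink for set-to-set cuts
  g2 <- igraph::add_vertices(g, 2)
  s <- n + 1L; t <- n + 2L
  el <- rbind(cbind(s, A), cbind(t, B))
  g2 <- igraph::add_edges(g2, t(el[, 1:2]),
                          attr = list(weight = rep(big, nrow(el))))
  fl <- igraph::max_flow(g2, source = s, target = t,
                         capacity = igraph::E(g2)$weight)
  cut <- fl$value
  if (cut >= big) stop("internal error: infinite-capacity edge cut")
  barrier <- if (cut <= 0) Inf else -net$kBT * log(cut / net$n_total)
  part1 <- setdiff(as.integer(fl$partition1), c(s, t))
  list(barrier = barrier, cut_value = cut, cut_A = part1)
}

#' Build the transition disconnectivity graph
#'
#' Pairwise min-cut barriers between all minima are ultrametric (a consequence
#' of max-flow's Gomory-Hu structure), so the TRDG is their single-linkage
#' merge tree: leaves at the node free energies, internal nodes at the
#' barriers.  Disconnected pairs are merged last at a sentinel barrier and
#' flagged.
#'
#' @param net a `transition_network`.
#' @param annotations optional data frame with one row per node (e.g.
#'   `chi_min`, `chi_max`, `frac_fibril` from member frames), carried on the
#'   leaves.
#' @return object of class `trdg`: `hclust` merge structure, `leaf_F`,
#'   `barriers` (matrix), `annotations`, `disconnected` flag.
#' @export
build_trdg <- function(net, annotations = NULL) {
  n <- nrow(net$sym)
  if (n == 1L) {
    return(structure(list(hc = NULL, leaf_F = net$free_energy,
                          barriers = matrix(0, 1, 1),
                          annotations = annotations, disconnected = FALSE),
                     class = "trdg"))
  }
  B <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    B[i, j] <- B[j, i] <- mincut_barrier(net, i, j)$barrier
  }
  disconnected <- any(!is.finite(B[upper.tri(B)]))
  Bf <- B
  if (disconnected) {
    mx <- max(Bf[is.finite(Bf)], net$free_energy)
    Bf[!is.finite(Bf)] <- mx + 10 * net$kBT
  }
  # a merge cannot sit below the leaves it joins
  floor_h <- outer(net$free_energy, net$free_energy, pmax)
  Bf <- pmax(Bf, floor_h)
  hc <- stats::hclust(stats::as.dist(Bf), method = "single")
  structure(list(hc = hc, leaf_F = net$free_energy, barriers = B,
                 annotations = annotations, disconnected = disconnected),
            class = "trdg")
}

#' @export
print.trdg <- function(x, ...) {
  cat("trdg:", length(x$leaf_F), "minima; ground state F =",
      signif(min(x$leaf_F), 4), "kcal/mol",
      if (x$disconnected) "(disconnected components present)" else "", "\n")
  invisible(x)
}

# Number of live branches at free energy F: clusters of the tree cut at
# height F that already contain at least one leaf born (F_leaf <= F).
.branches_alive <- function(tree, F) {
  lf <- tree$leaf_F
  if (is.null(tree$hc)) return(as.integer(sum(lf <= F) > 0))
  memb <- stats::cutree(tree$hc, h = F)
  length(unique(memb[lf <= F]))
}

#' Landscape roughness density profile
#'
#' Levy-Becker-style branch-splitting density of the TRDG: per free-energy bin
#' of width `dF`, the number of coexisting branches minus one, normalised by
#' the total number of minima and the bin width.  When leaf annotations carry
#' a `frac_fibril` column, the mean fibril-like fraction of the minima whose
#' free energy falls in each bin is overlaid.
#'
#' @param tree a `trdg`.
#' @param dF bin width in kcal/mol (> 0).
#' @param F_range optional range; defaults to (min leaf F, top merge).
#' @return data frame with `F_mid`, `rho` and (if annotated) `frac_fibril`.
#' @export
roughness_profile <- function(tree, dF = 0.2, F_range = NULL) {
  stopifnot(dF > 0)
  n_min <- length(tree$leaf_F)
  top <- if (is.null(tree$hc)) max(tree$leaf_F) else max(tree$hc$height)
  if (is.null(F_range)) F_range <- c(min(tree$leaf_F), top)
  edges <- seq(F_range[1], F_range[2] + dF, by = dF)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  rho <- vapply(mids, function(f)
    max(.branches_alive(tree, f) - 1L, 0L) / (n_min * dF), numeric(1))
  out <- data.frame(F_mid = mids, rho = rho)
  ann <- tree$annotations
  if (!is.null(ann) && "frac_fibril" %in% names(ann)) {
    bin <- findInterval(tree$leaf_F, edges, rightmost.closed = TRUE)
    out$frac_fibril <- vapply(seq_along(mids), function(b) {
      v <- ann$frac_fibril[bin == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  out
}

#' Annotate network nodes with fibril-overlap statistics
#'
#' For every cluster, the minimum and maximum overlap among member frames and
#' the fraction of members with `chi >= chi_c` (against the best reference).
#'
#' @param trajs list of trajectories (frame arrays or `sop_trajectory`).
#' @param labels list of per-trajectory label vectors (as in
#'   `cluster_model$labels`).
#' @param refs list of [reference_structure()].
#' @param chi_c overlap threshold.
#' @param n_states number of clusters.
#' @return data frame with `chi_min`, `chi_max`, `frac_fibril` per cluster.
#' @export
annotate_nodes <- function(trajs, labels, refs, chi_c = 0.30,
                           n_states = max(unlist(labels))) {
  if (!is.list(trajs) || inherits(trajs, "sop_trajectory")) trajs <- list(trajs)
  chi <- unlist(lapply(trajs, function(tr) {
    fr <- trajectory_frames(tr)
    apply(fr, 1, function(x)
      max(vapply(refs, function(r) chi_fib(x, r), numeric(1))))
  }))
  lab <- unlist(labels)
  stopifnot(length(chi) == length(lab))
  do.call(rbind, lapply(seq_len(n_states), function(s) {
    v <- chi[lab == s]
    data.frame(chi_min = if (length(v)) min(v) else NA_real_,
               chi_max = if (length(v)) max(v) else NA_real_,
               frac_fibril = if (length(v)) mean(v >= chi_c) else NA_real_)
  }))
}
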