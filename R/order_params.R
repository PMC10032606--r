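# Structural observables: the fibril-overlap order parameter chi_fib, DRID
# feature vectors, interchain contacts and the radius of gyration.  All are
# functions of interbead distances only, hence invariant under rigid motions.

#' Reference structure for the fibril-overlap order parameter
#'
#' chi_fib compares a conformation's pairwise bead distances against the
#' distances `r0` of a reference pair list: the overlap is the fraction of
#' pairs whose deviation is strictly within the tolerance `d`.
#'
#' @param coords reference bead coordinates (n x 3), or `NULL` if `pair_list`
#'   is given directly.
#' @param pair_list data frame with columns `i`, `j` (bead indices in the
#'   conformation to be evaluated) and `r0` (reference distance, Angstrom); if
#'   `NULL`, built from `coords` with [build_pair_list()].
#' @param topo topology used to locate backbone beads when building the pair
#'   list from `coords`.
#' @param d tolerance in Angstrom (default 2, of the order of a bead radius).
#' @param label polymorph label, e.g. `"U-bend"`.
#' @param min_sep minimum residue separation of pairs built from `coords`.
#' @return object of class `reference_structure`.
#' @export
reference_structure <- function(coords = NULL, pair_list = NULL, topo = NULL,
                                d = 2, label = "ref", min_sep = 3L) {
  if (is.null(pair_list)) {
    if (is.null(coords) || is.null(topo))
      stop("need either pair_list or coords + topo")
    pair_list <- build_pair_list(coords, topo, min_sep = min_sep)
  }
  stopifnot(nrow(pair_list) >= 1, all(pair_list$r0 > 0), d > 0)
  structure(list(coords = coords, pair_list = pair_list, d = d, label = label),
            class = "reference_structure")
}

#' Backbone pair list from a reference conformation
#'
#' BB-BB pairs with residue separation at least `min_sep`, carrying their
#' reference distances; trivially bonded pairs are thereby excluded while
#' distance topology (turns, strand registry) is retained.
#'
#' @param coords reference coordinates matching `topo`.
#' @param topo an `sop_topology`.
#' @param min_sep minimum residue separation.
#' @return data frame `i`, `j`, `r0`.
#' @export
build_pair_list <- function(coords, topo, min_sep = 3L) {
  bb <- bb_indices(topo)
  res <- topo$beads$res[bb]
  pr <- which(outer(res, res, function(a, b) b - a) >= min_sep, arr.ind = TRUE)
  i <- bb[pr[, 1]]; j <- bb[pr[, 2]]
  r0 <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  data.frame(i = i, j = j, r0 = r0)
}

#' Fibril-overlap order parameter
#'
#' Fraction of reference pairs whose distance deviates from the reference by
#' strictly less than the tolerance `d`; 1 for the reference geometry itself,
#' 0 for a fully dissimilar chain.
#'
#' @param conf coordinate matrix covering all beads in the reference pair
#'   list.
#' @param ref a [reference_structure()].
#' @return overlap in `[0, 1]`.
#' @export
chi_fib <- function(conf, ref) {
  pl <- ref$pair_list
  if (max(pl$i, pl$j) > nrow(conf))
    stop("pair list indexes beads beyond the conformation")
  r <- sqrt(rowSums((conf[pl$i, , drop = FALSE] - conf[pl$j, , drop = FALSE])^2))
  mean(abs(r - pl$r0) < ref$d)
}

#' Classify a conformation against fibril references
#'
#' A conformation is assembly-competent (an N* state) if its overlap with some
#' reference reaches the threshold `chi_c`; among qualifying references the
#' one with the highest overlap wins (ties broken by list order).  Otherwise
#' the conformation is a random coil, `"RC"`.
#'
#' @param conf coordinate matrix.
#' @param refs list of [reference_structure()] objects (named or labelled).
#' @param chi_c positive overlap threshold; the conformation qualifies when
#'   `chi >= chi_c` (default 0.30; a value above 1 labels everything RC).
#' @return label string (reference label or `"RC"`) with attribute `"chi"`
#'   holding the per-reference overlaps.
#' @export
classify_nstar <- function(conf, refs, chi_c = 0.30) {
  if (length(refs) == 0L) stop("empty reference list")
  stopifnot(chi_c > 0)
  chis <- vapply(refs, function(r) chi_fib(conf, r), numeric(1))
  labs <- vapply(refs, function(r) r$label, character(1))
  names(chis) <- labs
  ok <- chis >= chi_c
  lab <- if (any(ok)) labs[ok][which.max(chis[ok])] else "RC"
  structure(lab, chi = chis)
}

#' DRID feature vector
#'
#' Distribution-of-reciprocal-interatomic-distances features: for each
#' centroid bead (all backbone beads by default) the mean of reciprocal
#' distances to eligible partners, the square root of their second central
#' moment and the signed cube root of the third.  Partners exclude the
#' centroid itself and its bonded neighbours.
#'
#' @param conf coordinate matrix.
#' @param topo an `sop_topology`.
#' @param centroids bead indices to use as centroids (default: backbone
#'   beads).
#' @return object of class `drid_vector`: 3 x n_centroids matrix (rows mu,
#'   nu, xi).
#' @export
drid_vector <- function(conf, topo, centroids = NULL) {
  if (is.null(centroids)) centroids <- bb_indices(topo)
  n <- nrow(conf)
  if (n < 3L) stop("need at least 3 beads")
  nb <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds$i[k]; j <- topo$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  out <- vapply(centroids, function(c0) {
    part <- setdiff(seq_len(n), c(c0, nb[[c0]]))
    r <- sqrt(rowSums((conf[part, , drop = FALSE] -
                         matrix(conf[c0, ], length(part), 3, byrow = TRUE))^2))
    if (any(r < 1e-9)) stop("coincident beads at centroid ", c0)
    d <- 1 / r
    mu <- mean(d)
    m2 <- mean((d - mu)^2)
    m3 <- mean((d - mu)^3)
    c(mu, sqrt(m2), sign(m3) * abs(m3)^(1 / 3))
  }, numeric(3))
  rownames(out) <- c("mu", "nu", "xi")
  structure(out, class = "drid_vector")
}

#' DRID distance between two conformations
#'
#' Euclidean norm over the concatenated per-centroid triplets, normalised by
#' the number of centroid components.
#'
#' @param v1,v2 `drid_vector` objects (or plain 3 x n matrices).
#' @return non-negative distance.
#' @export
drid_distance <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  sqrt(sum((unclass(v1) - unclass(v2))^2) / length(v1))
}

#' DRID feature matrix for a trajectory
#'
#' @param traj an `sop_trajectory` or frames array.
#' @param topo an `sop_topology`.
#' @param centroids see [drid_vector()].
#' @return n_frames x (3 * n_centroids) matrix.
#' @export
drid_features <- function(traj, topo, centroids = NULL) {
  fr <- trajectory_frames(traj)
  t(apply(fr, 1, function(x) as.vector(drid_vector(x, topo, centroids))))
}

#' Interchain contact count and dimer call
#'
#' A contact is any pair of beads on different chains within `cutoff`
#' (boundary inclusive); a dimer is called when the count strictly exceeds 5.
#'
#' @param confA,confB coordinate matrices of the two chains.
#' @param cutoff contact distance in Angstrom (default 6).
#' @return list with `n_contacts` and `is_dimer`.
#' @export
interchain_contacts <- function(confA, confB, cutoff = 6) {
  stopifnot(is.matrix(confA), is.matrix(confB), cutoff > 0)
  d2 <- outer(rowSums(confA^2), rowSums(confB^2), "+") -
    2 * tcrossprod(confA, confB)
  n <- sum(d2 <= cutoff^2 + 1e-12)
  list(n_contacts = n, is_dimer = n > 5)
}

#' Radius of gyration
#'
#' Mass-uniform R_g over all beads.
#'
#' @param conf coordinate matrix.
#' @return R_g in Angstrom.
#' @export
radius_of_gyration <- function(conf) {
  if (!is.matrix(conf)) conf <- matrix(conf, ncol = 3)
  ctr <- colMeans(conf)
  sqrt(mean(rowSums((conf - matrix(ctr, nrow(conf), 3, byrow = TRUE))^2)))
}
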