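# Shared objects for the suite: the shipped force field, small topologies and
# a jittered-chain generator.  Everything is built in code at test time.

FF <- load_forcefield()

small_topology <- function(seq = "ACDEFG") build_topology(parse_sequence(seq), FF)

# extended chain + Gaussian jitter, guaranteed bond-valid
jittered_chain <- function(topo, sd = 0.3, seed = 1) {
  set.seed(seed)
  extended_conformation(topo) +
    matrix(rnorm(3 * nrow(topo$beads), sd = sd), ncol = 3)
}

# random rigid motion applied to a conformation
rigid_transform <- function(conf, seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                2 * (q[2] * q[4] + q[1] * q[3]),
                2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                2 * (q[3] * q[4] - q[1] * q[2]),
                2 * (q[2] * q[4] - q[1] * q[3]),
                2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
              3, 3, byrow = TRUE)
  conf %*% t(R) + matrix(rnorm(3) * 10, nrow(conf), 3, byrow = TRUE)
}

# bare topology carcass for order-parameter tests that need no force field
bare_topology <- function(n_beads, bonds = NULL) {
  structure(list(
    beads = data.frame(index = seq_len(n_beads), res = seq_len(n_beads),
                       site = "BB", aa = "A", charge = 0, sigma = 3.8,
                       chain = 1L),
    bonds = if (is.null(bonds))
      data.frame(i = integer(0), j = integer(0), r0 = numeric(0)) else bonds,
    n_res = n_beads, id = "bare", chain = 1L), class = "sop_topology")
}

# hand-built transition network from a symmetric count matrix
manual_network <- function(sym, lag = 1L, temperature = 298) {
  sym <- as.matrix(sym)
  pi <- rowSums(sym) / sum(sym)
  kBT <- thermal_energy(temperature)
  structure(list(counts = sym, sym = sym, pi = pi,
                 free_energy = -kBT * log(pi), lag = lag, lag_ps = NULL,
                 kBT = kBT, n_total = sum(sym)),
            class = "transition_network")
}

# brute-force min cut between s and t: enumerate all 2-partitions
brute_force_mincut <- function(sym, s, t) {
  n <- nrow(sym)
  cap <- 2 * sym
  others <- setdiff(seq_len(n), c(s, t))
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    side_s <- c(s, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    side_t <- setdiff(seq_len(n), side_s)
    cut <- sum(cap[side_s, side_t, drop = FALSE])
    best <- min(best, cut)
  }
  best
}
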