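test_that("transition counting follows the sliding-window contract", {
  net <- count_transitions(c(1, 1, 2, 2), lag = 1)
  expect_equal(net$counts, matrix(c(1, 0, 1, 1), 2, 2))
  expect_equal(net$n_total, 3)
  # no counting across trajectory boundaries
  net2 <- count_transitions(list(c(1, 1), c(2, 2)), lag = 1)
  expect_equal(net2$counts[1, 2], 0)
  expect_equal(net2$counts[1, 1], 1)
  expect_equal(net2$counts[2, 2], 1)
  expect_error(count_transitions(integer(0)), "empty")
  # symmetrised counts are symmetric; free energies from stationary weights
  net3 <- count_transitions(c(1, 2, 1, 1, 3, 2), lag = 1)
  expect_equal(net3$sym, t(net3$sym))
  expect_equal(sum(net3$pi), 1)
  expect_equal(net3$free_energy, -net3$kBT * log(net3$pi))
})

test_that("long uniform label streams give uniform stationary weights", {
  set.seed(14)
  lab <- sample.int(3, 6000, replace = TRUE)
  net <- count_transitions(lab, lag = 1)
  expect_lt(max(abs(net$pi - 1 / 3)), 0.03)
})

test_that("knee-point clustering recovers three planted DRID blobs", {
  set.seed(7)
  centers <- matrix(c(0, 0, 0, 0, 0, 0,
                      5, 5, 0, 0, 0, 0,
                      0, 0, 6, 6, 0, 0), 3, 6, byrow = TRUE)
  truth <- rep(1:3, each = 60)
  X <- centers[truth, ] + matrix(rnorm(180 * 6, sd = 0.3), 180, 6)
  cm <- cluster_trajectories(list(X), k_range = 1:6, seed = 2)
  expect_equal(cm$k, 3L)
  # one planted blob per recovered cluster
  tab <- table(truth, cm$labels[[1]])
  expect_true(all(rowSums(tab > 0) == 1), info = "pure clusters")
  # permuting the frames permutes labels only
  perm <- sample(180)
  cm2 <- cluster_trajectories(list(X[perm, ]), k_range = 1:6, seed = 2)
  expect_equal(cm2$k, 3L)
  tab2 <- table(cm$labels[[1]][perm], cm2$labels[[1]])
  expect_true(all(rowSums(tab2 > 0) == 1))
})

test_that("degenerate input collapses to a single cluster with a warning", {
  X <- matrix(1, 40, 4)
  expect_warning(cm <- cluster_trajectories(list(X), k_range = 1:5), "identical")
  expect_equal(cm$k, 1L)
})

test_that("min-cut barrier matches hand enumeration on the 3-node chain", {
  # symmetric counts 1-2: 5, 2-3: 1; total count 12; undirected capacities
  # 10 and 2 -> min cut separating 1 from 3 is 2
  sym <- matrix(0, 3, 3)
  sym[1, 2] <- sym[2, 1] <- 5
  sym[2, 3] <- sym[3, 2] <- 1
  net <- manual_network(sym)
  mb <- mincut_barrier(net, 1, 3)
  expect_equal(mb$cut_value, 2)
  expect_equal(mb$barrier, net$kBT * log(6), tolerance = 1e-12)
  # symmetry of the cut
  expect_equal(mincut_barrier(net, 3, 1)$cut_value, mb$cut_value)
  # disconnected components: infinite barrier, reported explicitly
  sym2 <- matrix(0, 4, 4)
  sym2[1, 2] <- sym2[2, 1] <- 3
  sym2[3, 4] <- sym2[4, 3] <- 2
  expect_equal(mincut_barrier(manual_network(sym2), 1, 4)$barrier, Inf)
})

test_that("min-cut equals exhaustive enumeration on random small networks", {
  set.seed(33)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    sym <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.7) sym[i, j] <- sym[j, i] <- sample(1:9, 1)
    }
    if (all(sym == 0)) next
    net <- manual_network(sym)
    st <- sample(n, 2)
    expect_equal(mincut_barrier(net, st[1], st[2])$cut_value,
                 brute_force_mincut(sym, st[1], st[2]))
  }
})

test_that("adding transition counts to an edge never raises a barrier", {
  set.seed(44)
  sym <- matrix(0, 5, 5)
  for (i in 1:4) sym[i, i + 1] <- sym[i + 1, i] <- sample(2:8, 1)
  sym[1, 3] <- sym[3, 1] <- 2
  net <- manual_network(sym)
  b0 <- mincut_barrier(net, 1, 5)
  sym2 <- sym
  sym2[2, 3] <- sym2[3, 2] <- sym[2, 3] + 5
  b1 <- mincut_barrier(manual_network(sym2), 1, 5)
  # more capacity can only raise (or preserve) the flow between the sets
  expect_gte(b1$cut_value, b0$cut_value)
  # at fixed total counts the barrier cannot increase
  expect_lte(-log(b1$cut_value), -log(b0$cut_value))
})

test_that("TRDG assembles merges in min-cut order with ultrametric barriers", {
  # two fast pairs joined by one slow bridge
  sym <- matrix(0, 4, 4)
  sym[1, 2] <- sym[2, 1] <- 20
  sym[3, 4] <- sym[4, 3] <- 18
  sym[2, 3] <- sym[3, 2] <- 2
  net <- manual_network(sym)
  tree <- build_trdg(net)
  hc <- tree$hc
  # first two merges join the strongly connected pairs, the bridge comes last
  expect_equal(sort(hc$height)[3], max(hc$height))
  memb <- cutree(hc, k = 2)
  expect_equal(unname(memb), c(1, 1, 2, 2))
  # two-minima network: single merge at the pair's min-cut barrier
  sym2 <- matrix(c(40, 4, 4, 40), 2, 2)
  net2 <- manual_network(sym2)
  tree2 <- build_trdg(net2)
  expect_equal(tree2$hc$height, mincut_barrier(net2, 1, 2)$barrier)
  # ultrametric triangle inequality on random connected networks
  set.seed(55)
  for (rep in 1:5) {
    n <- 6
    s <- matrix(0, n, n)
    for (i in 1:(n - 1)) s[i, i + 1] <- s[i + 1, i] <- sample(1:9, 1)
    s[1, 4] <- s[4, 1] <- sample(1:9, 1)
    netr <- manual_network(s)
    B <- build_trdg(netr)$barriers
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      if (length(unique(c(i, j, k))) == 3)
        expect_lte(B[i, k], max(B[i, j], B[j, k]) + 1e-9)
    }
  }
})

test_that("roughness density counts coexisting branches per energy bin", {
  # single minimum: no splitting anywhere
  one <- build_trdg(manual_network(matrix(2, 1, 1)))
  prof1 <- roughness_profile(one, dF = 0.2)
  expect_true(all(prof1$rho == 0))
  # two minima: rho = 1 / (2 dF) in bins between birth and merge
  sym <- matrix(c(8, 1, 1, 8), 2, 2)
  net <- manual_network(sym)
  tree <- build_trdg(net)
  dF <- 0.1
  prof <- roughness_profile(tree, dF = dF)
  live <- prof$rho > 0
  expect_true(any(live))
  expect_equal(unique(prof$rho[live]), 1 / (2 * dF), tolerance = 1e-12)
  # doubling the bin width halves the peak density
  prof2 <- roughness_profile(tree, dF = 2 * dF)
  expect_equal(max(prof2$rho), max(prof$rho) / 2, tolerance = 1e-12)
  expect_error(roughness_profile(tree, dF = 0), "dF")
})
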