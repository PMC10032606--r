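test_that("dimer setup places chains at the target COM separation", {
  U <- make_toy_reference("hairpin-U", ff = FF)
  topo <- attr(U, "topology")
  tU <- attr(U, "template")
  sys <- setup_dimer(tU, tU, topo, topo, FF, separation = 12, seed = 3)
  comA <- colMeans(sys$coords[1:sys$n_A, ])
  comB <- colMeans(sys$coords[-(1:sys$n_A), ])
  expect_equal(sqrt(sum((comA - comB)^2)), 12, tolerance = 1e-6)
  expect_error(setup_dimer(tU, tU, topo, topo, FF, separation = 0), "positive")
  # seeded determinism of the initial pose
  sys2 <- setup_dimer(tU, tU, topo, topo, FF, separation = 12, seed = 3)
  expect_identical(sys$coords, sys2$coords)
  sys3 <- setup_dimer(tU, tU, topo, topo, FF, separation = 12, seed = 4)
  expect_false(identical(sys$coords, sys3$coords))
})

test_that("interchain parameters equal the intrachain ones for the same pair", {
  t1 <- small_topology("ACDE")
  dimt <- merge_topologies(t1, t1)
  sysd <- sop_system(dimt, FF)
  sys1 <- sop_system(t1, FF)
  cA <- jittered_chain(t1, seed = 61)
  cB <- jittered_chain(t1, seed = 62) + matrix(c(6, 2, 1), 8, 3, byrow = TRUE)
  eAB <- sop_energy(rbind(cA, cB), sys = sysd)$total
  eA <- sop_energy(cA, sys = sys1)$total
  eB <- sop_energy(cB, sys = sys1)$total
  # independent brute-force interchain sum built from the parameter tables
  b <- t1$beads
  g <- FF$globals
  inter <- 0
  for (i in seq_len(8)) for (j in seq_len(8)) {
    r <- sqrt(sum((cA[i, ] - cB[j, ])^2))
    si <- b$site[i]; sj <- b$site[j]
    sig <- (b$sigma[i] + b$sigma[j]) / 2
    eps <- if (si == "BB" && sj == "BB") g$eps_bb
           else if (si == "SC" && sj == "SC") FF$eps_ss[b$aa[i], b$aa[j]]
           else g$eps_bs
    sr6 <- (sig / r)^6
    inter <- inter + eps * (sr6^2 - 2 * sr6)
    qq <- b$charge[i] * b$charge[j]
    if (qq != 0)
      inter <- inter + idpscape:::.KE_COULOMB / g$dielectric * qq *
        exp(-r / g$debye_length) / r
  }
  expect_equal(eAB - eA - eB, inter, tolerance = 1e-9)
})

test_that("COM restraint holds the mean separation near the target", {
  U <- make_toy_reference("hairpin-U", ff = FF)
  topo <- attr(U, "topology"); tU <- attr(U, "template")
  sys <- setup_dimer(tU, tU, topo, topo, FF, separation = 14, stiffness = 5,
                     seed = 9)
  cfg <- bd_config(n_steps = 4000, save_stride = 50, seed = 9)
  dtr <- run_dimerization(sys, cfg)
  fr <- dtr$traj$frames
  sep <- apply(fr, 1, function(x) {
    sqrt(sum((colMeans(x[1:24, ]) - colMeans(x[25:48, ]))^2))
  })
  expect_lt(abs(mean(sep[-(1:10)]) - 14), 1.5)
})

test_that("purely repulsive chains never register contacts", {
  U <- make_toy_reference("hairpin-U", ff = FF)
  topo <- attr(U, "topology"); tU <- attr(U, "template")
  sys <- setup_dimer(tU, tU, topo, topo, FF, separation = 22, seed = 5)
  # replace every interchain interaction by a hard long-range repulsion
  inter <- sys$sys$pairs$i <= 24 & sys$sys$pairs$j > 24
  sys$sys$pairs$cls[inter] <- "EXV"
  sys$sys$pairs$sigma[inter] <- 8
  sys$sys$pairs$eps[inter] <- 5
  cfg <- bd_config(n_steps = 1500, save_stride = 50, seed = 5)
  dtr <- run_dimerization(sys, cfg)
  expect_true(all(dtr$n_contacts == 0))
})

test_that("complementary rigid hairpins at close range form a dimer", {
  sq <- strrep("I", 12)
  U <- make_toy_reference("hairpin-U", n_res = 12, sequence = sq, ff = FF)
  topo <- attr(U, "topology"); tU <- attr(U, "template")
  sys <- setup_dimer(tU, tU, topo, topo, FF, separation = 11, seed = 2)
  cfg <- bd_config(n_steps = 2500, save_stride = 50, seed = 2)
  dtr <- run_dimerization(sys, cfg)
  expect_gt(max(dtr$n_contacts), 5)
  expect_true(any(dtr$n_contacts > 5))
})

test_that("Baum-Welch recovers a planted two-state Gaussian emitter", {
  A <- matrix(c(0.95, 0.05, 0.02, 0.98), 2, 2, byrow = TRUE)
  mu <- rbind(c(0, 0), c(3, 3))
  set.seed(71)
  n <- 2000
  s <- integer(n); s[1] <- 1
  for (t in 2:n) s[t] <- sample.int(2, 1, prob = A[s[t - 1], ])
  X <- mu[s, ] + matrix(rnorm(2 * n, sd = 0.5), n, 2)
  fit <- fit_gaussian_hmm(X, 2, seed = 1)
  # identify states by emission means
  ord <- order(fit$means[, 1])
  Ahat <- fit$transmat[ord, ord]
  expect_lt(max(abs(Ahat - A)), 0.05)
  # EM likelihood is non-decreasing
  expect_true(all(diff(fit$loglik) > -1e-6))
  # single state: trivial self-transition network
  net1 <- fit_hmm_network(X, 1)
  expect_equal(unname(net1$transmat[1, 1]), 1)
  expect_equal(unname(net1$populations), 1)
})

test_that("HMM network labels states by composition and exports tables", {
  # synthetic features: (chiU_A, chiS_A, chiU_B, chiS_B, n_contacts)
  set.seed(81)
  mk <- function(mu, n) matrix(rep(mu, each = n), n) +
    matrix(rnorm(n * 5, sd = 0.03), n)
  X <- rbind(mk(c(0.6, 0.1, 0.6, 0.1, 9), 300),   # U-U dimer
             mk(c(0.05, 0.05, 0.05, 0.08, 1), 300))  # RC-RC monomers
  netw <- fit_hmm_network(X, 2, ref_labels = c("U", "S"), seed = 2)
  expect_setequal(netw$state_labels, c("U-U dimer", "RC-RC"))
  expect_equal(sum(netw$populations), 1, tolerance = 1e-9)
  d <- file.path(tempdir(), "hmmnet")
  fn <- export_hmm_network(netw, d)
  expect_true(all(file.exists(fn)))
  nodes <- read.delim(file.path(d, "nodes.tsv"))
  expect_equal(nrow(nodes), 2)
  unlink(d, recursive = TRUE)
})
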