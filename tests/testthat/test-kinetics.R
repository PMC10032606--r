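test_that("transition matrix is the row normalisation of symmetrised counts", {
  tm <- transition_matrix(matrix(c(9, 1, 1, 9), 2, 2))
  expect_equal(tm$T, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  expect_equal(rowSums(tm$T), c(1, 1))
  # absorbing zero-count state rejected with its id
  bad <- matrix(c(3, 0, 1, 0), 2, 2, byrow = TRUE)
  bad[2, ] <- 0
  expect_error(transition_matrix(bad), "2")
})

test_that("implied timescales follow t = -lag / log|lambda|", {
  tm <- transition_matrix(matrix(c(9, 1, 1, 9), 2, 2))
  ts <- implied_timescales(tm, lag = 1)
  expect_equal(ts$eigenvalue, 0.8, tolerance = 1e-12)
  expect_equal(ts$timescale, -1 / log(0.8), tolerance = 1e-12)
  expect_equal(ts$timescale, 4.4814, tolerance = 1e-4)
  T2 <- matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2)   # lambda_2 = 0.5
  ts2 <- implied_timescales(T2, lag = 1)
  expect_equal(ts2$timescale, 1 / log(2), tolerance = 1e-10)
  # relabeling invariance
  set.seed(10)
  C <- matrix(sample(1:20, 16, replace = TRUE), 4, 4)
  C <- C + t(C)
  perm <- c(3, 1, 4, 2)
  t_a <- implied_timescales(transition_matrix(C), lag = 1)$timescale
  t_b <- implied_timescales(transition_matrix(C[perm, perm]), lag = 1)$timescale
  expect_equal(t_a, t_b, tolerance = 1e-9)
  # detailed-balance counts give a purely real spectrum
  ev <- idpscape:::.tm_eigen(transition_matrix(C)$T, transition_matrix(C)$pi)
  expect_true(all(abs(Im(ev)) == 0))
})

test_that("implied timescales are flat across lags for exact Markov data", {
  P <- matrix(c(0.96, 0.03, 0.01,
                0.03, 0.94, 0.03,
                0.01, 0.03, 0.96), 3, 3, byrow = TRUE)
  set.seed(6)
  lab <- integer(30000)
  lab[1] <- 1
  for (t in 2:length(lab)) lab[t] <- sample.int(3, 1, prob = P[lab[t - 1], ])
  t_at <- vapply(c(1, 2, 4), function(lg) {
    implied_timescales(transition_matrix(count_transitions(lab, lag = lg)),
                       lag = lg)$timescale[1]
  }, numeric(1))
  expect_lt(max(abs(t_at - mean(t_at))) / mean(t_at), 0.15)
})

test_that("graph-transformation MFPT matches closed forms and the linear solve", {
  # two-state chain with escape probability 0.1 -> 10 steps
  P <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(mfpt_graph_transform(P, 1, 2)$mfpt, 10, tolerance = 1e-12)
  # source equals target -> 0
  expect_equal(mfpt_graph_transform(P, 1, 1)$mfpt, 0)
  # random chains against the independent linear-system oracle
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    P <- matrix(runif(n * n) + 1e-3, n)
    P <- P / rowSums(P)
    tgt <- sample(n, 1)
    src <- sample(setdiff(1:n, tgt), 1)
    gt <- mfpt_graph_transform(P, src, tgt)$mfpt
    m <- solve(diag(n - 1) - P[-tgt, -tgt], rep(1, n - 1))
    idx <- which(setdiff(1:n, tgt) == src)
    expect_equal(gt, m[idx], tolerance = 1e-8)
  }
  # unreachable target -> infinite, reported
  Pd <- diag(2)
  expect_equal(mfpt_graph_transform(Pd, 1, 2)$mfpt, Inf)
})

test_that("FPT statistics: mean, jackknife error, and distribution diagnostics", {
  s <- fpt_statistics(rep(5, 8))
  expect_equal(s$mean, 5)
  expect_equal(s$se_jackknife, 0)
  # exponential samples: mean recovered, Poissonian diagnostic accepted
  set.seed(23)
  x <- rexp(5000, rate = 1 / 25)
  se_x <- fpt_statistics(x)
  expect_lt(abs(se_x$mean - 25), 3 * se_x$se_jackknife)
  expect_true(se_x$exponential$ok)
  # jackknife SE of the mean agrees with the classical formula
  expect_equal(se_x$se_jackknife, sd(x) / sqrt(length(x)), tolerance = 1e-10)
  # well-separated bimodal mixture: single log-Gaussian flagged poor
  set.seed(24)
  bim <- c(exp(rnorm(400, 0, 0.15)), exp(rnorm(400, 5, 0.15)))
  sb <- fpt_statistics(bim)
  expect_false(sb$log_gaussian$ok)
  # censoring bookkeeping
  sc <- fpt_statistics(c(2, 3, 10), censored = c(FALSE, FALSE, TRUE))
  expect_equal(sc$n, 2L)
  expect_equal(sc$censor_fraction, 1 / 3)
  expect_error(fpt_statistics(5), "at least 2")
})

test_that("first-passage extraction converts frames to physical time", {
  U <- make_toy_reference("hairpin-U", ff = FF)
  S <- make_toy_reference("meander-S", ff = FF)
  E <- attr(make_toy_reference("extended", ff = FF), "template")
  tU <- attr(U, "template")
  # frames 1..7 disordered (extended), frame 8 enters the N* class
  nb <- nrow(tU)
  frames <- array(0, c(10, nb, 3))
  for (t in 1:10) frames[t, , ] <- if (t < 8) E else tU
  traj <- structure(list(frames = frames, dt_save_ps = 660, duration_ps = 5940,
                         cfg = list(seed = 1)), class = "sop_trajectory")
  fp <- first_passage_from_trajectories(list(traj), list(U, S),
                                        direction = "RC->N*")
  expect_equal(fp$tau, 7 * 660)          # 4.62 ns
  expect_false(fp$censored)
  # a trajectory that never arrives is censored at its length
  frames2 <- frames; for (t in 1:10) frames2[t, , ] <- E
  traj2 <- structure(list(frames = frames2, dt_save_ps = 660,
                          duration_ps = 5940, cfg = list(seed = 1)),
                     class = "sop_trajectory")
  fp2 <- first_passage_from_trajectories(list(traj2), list(U, S),
                                         direction = "RC->N*")
  expect_true(fp2$censored)
  # a start already inside the target class is excluded with a warning
  frames3 <- frames; frames3[1, , ] <- tU
  traj3 <- structure(list(frames = frames3, dt_save_ps = 660,
                          duration_ps = 5940, cfg = list(seed = 1)),
                     class = "sop_trajectory")
  expect_warning(
    fp3 <- first_passage_from_trajectories(list(traj3), list(U, S),
                                           direction = "RC->N*"),
    "target class")
  expect_equal(nrow(fp3), 0L)
  expect_equal(attr(fp3, "n_degenerate"), 1L)
  # directed transitions between polymorph classes
  tS <- attr(S, "template")
  frames4 <- frames
  frames4[1:4, , ] <- frames4[rep(1, 4) * 0 + 1, , ]   # keep RC start
  for (t in 1:4) frames4[t, , ] <- tU
  frames4[5, , ] <- tS
  traj4 <- structure(list(frames = frames4, dt_save_ps = 100,
                          duration_ps = 900, cfg = list(seed = 1)),
                     class = "sop_trajectory")
  fp4 <- first_passage_from_trajectories(list(traj4), list(U, S),
                                         direction = "hairpin-U->meander-S")
  expect_equal(fp4$tau, 4 * 100)
})

test_that("empirical MFPT converges to the graph-transformation value", {
  # 2-state toy chain with known rates; empirical FPT over many trajectories
  p <- 0.05
  P <- matrix(c(1 - p, p, 0.1, 0.9), 2, 2, byrow = TRUE)
  set.seed(31)
  taus <- vapply(1:300, function(i) {
    s <- 1L; t <- 0L
    while (s != 2L) { s <- sample.int(2, 1, prob = P[s, ]); t <- t + 1L }
    as.numeric(t)
  }, numeric(1))
  st <- fpt_statistics(taus)
  gt <- mfpt_graph_transform(P, 1, 2)$mfpt       # = 1/p = 20
  expect_equal(gt, 20, tolerance = 1e-12)
  expect_lt(abs(st$mean - gt), 3 * st$se_jackknife)
})
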