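test_that("natural time unit reproduces the pinned physical value and scales", {
  gamma <- friction_coefficient()          # default eta and bead radius
  expect_equal(natural_time_unit(gamma, 1, 1), 13.2, tolerance = 0.05 / 13.2)
  expect_equal(natural_time_unit(2 * gamma, 1, 1),
               2 * natural_time_unit(gamma, 1, 1))
  # SI sanity: 1 kg/s, 1 m, 1 J -> 1 s
  expect_equal(natural_time_unit(1, 1, 1), 1)
  expect_error(natural_time_unit(-1, 1, 1), "positive")
})

test_that("config reports physical duration from steps, dt and tau_HF", {
  cfg <- bd_config(n_steps = 8e6, dt = 0.05, save_stride = 1000)
  expect_equal(cfg$duration_ps * 1e-6, 5.3, tolerance = 0.05 / 5.3)
  cfg0 <- bd_config(n_steps = 0)
  expect_equal(cfg0$duration_ps, 0)
})

test_that("steppers are deterministic given the seed and honour limits", {
  topo <- small_topology("ACDEF")
  conf <- extended_conformation(topo)
  cfg <- bd_config(n_steps = 200, save_stride = 20, seed = 42)
  t1 <- run_trajectory(conf, topo, FF, cfg)
  t2 <- run_trajectory(conf, topo, FF, cfg)
  expect_identical(t1$frames, t2$frames)
  # zero steps: exactly the initial frame
  t0 <- run_trajectory(conf, topo, FF, bd_config(n_steps = 0))
  expect_equal(dim(t0$frames)[1], 1L)
  expect_equal(t0$frames[1, , ], conf)
  # zero force + zero thermal noise -> no displacement
  still <- idpscape:::.bd_kernel_free(conf, conf * 0, cfg$dt_ps, cfg$gamma,
                                      kBT = 0)
  expect_equal(still, conf)
})

test_that("free diffusion satisfies the Einstein relation", {
  cfg <- bd_config(n_steps = 40, save_stride = 40, seed = 1)
  D <- cfg$kBT / cfg$gamma
  t_phys <- 40 * cfg$dt_ps
  zero_force <- function(x) x * 0
  set.seed(99)
  seeds <- sample.int(1e6, 400)
  disp2 <- vapply(seeds, function(s) {
    cfg$seed <- s
    tr <- run_trajectory(matrix(0, 1, 3), cfg = cfg, force_fn = zero_force)
    sum(tr$frames[2, 1, ]^2)
  }, numeric(1))
  msd <- mean(disp2)
  se <- sd(disp2) / sqrt(length(disp2))
  expect_lt(abs(msd - 6 * D * t_phys), 3 * se)
})

test_that("harmonic bond samples the equipartition variance", {
  k <- 2; r0 <- 10
  bond_force <- function(x) {
    dv <- x[1, ] - x[2, ]
    r <- sqrt(sum(dv^2))
    f <- -k * (r - r0) * dv / r
    rbind(f, -f)
  }
  # dt = 0.01 tau_HF keeps the Euler discretisation bias of the bond-length
  # variance (factor 2 / (2 - k dt / gamma)) below one percent
  cfg <- bd_config(n_steps = 60000, dt = 0.01, save_stride = 20, seed = 5)
  init <- rbind(c(0, 0, 0), c(r0, 0, 0))
  tr <- run_trajectory(init, cfg = cfg, force_fn = bond_force)
  r <- apply(tr$frames, 1, function(x) sqrt(sum((x[1, ] - x[2, ])^2)))
  r <- r[-(1:100)]                      # discard equilibration
  v <- var(r)
  target <- cfg$kBT / k
  expect_lt(abs(v - target) / target, 0.10)
})

test_that("RPY mobility has the Stokes self-limit and stays positive definite", {
  gamma <- friction_coefficient()
  mu1 <- rpy_mobility(matrix(0, 1, 3), a_h = 4.86538, gamma = gamma)
  expect_equal(mu1, diag(1 / gamma, 3))
  # far-separated beads: off-diagonal coupling vanishes
  far <- rpy_mobility(rbind(c(0, 0, 0), c(0, 0, 1e6)), 4.86538, gamma)
  expect_lt(max(abs(far[1:3, 4:6])), 1e-5 / gamma)
  # random non-overlapping configuration: symmetric positive definite
  set.seed(8)
  topo <- small_topology("ACDEF")
  conf <- jittered_chain(topo, seed = 8)
  mu <- rpy_mobility(conf, 4.86538, gamma)
  expect_equal(mu, t(mu), tolerance = 1e-12)
  expect_gt(min(eigen(mu, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("hydrodynamics changes kinetics but not the stationary distribution", {
  k <- 2; r0 <- 10
  bond_force <- function(x) {
    dv <- x[1, ] - x[2, ]
    r <- sqrt(sum(dv^2))
    f <- -k * (r - r0) * dv / r
    rbind(f, -f)
  }
  init <- rbind(c(0, 0, 0), c(r0, 0, 0))
  get_mean_r <- function(hi, seed) {
    cfg <- bd_config(n_steps = 20000, save_stride = 10, seed = seed,
                     hydrodynamics = hi)
    tr <- run_trajectory(init, cfg = cfg, force_fn = bond_force)
    r <- apply(tr$frames, 1, function(x) sqrt(sum((x[1, ] - x[2, ])^2)))
    r[-(1:50)]
  }
  r_fd <- get_mean_r("none", 31)
  r_hi <- get_mean_r("rpy", 32)
  # the harmonic-bond equilibrium mean is identical under both propagators
  se <- sqrt(var(r_fd) / 500 + var(r_hi) / 500)   # conservative n_eff
  expect_lt(abs(mean(r_fd) - mean(r_hi)), 4 * se)
})

test_that("trajectory metadata round-trips through save/load", {
  topo <- small_topology("ACDEF")
  cfg <- bd_config(n_steps = 100, save_stride = 20, seed = 3)
  tr <- run_trajectory(extended_conformation(topo), topo, FF, cfg)
  path <- file.path(tempdir(), "traj_test.xyz")
  write_trajectory_xyz(tr, path, topo)
  back <- read_trajectory_xyz(path)
  expect_equal(dim(back$frames), dim(tr$frames))
  expect_lt(max(abs(back$frames - tr$frames)), 1e-3)
  expect_equal(back$dt_save_ps, tr$dt_save_ps)
  expect_equal(back$cfg$seed, cfg$seed)
  unlink(c(path, paste0(path, ".json")))
})
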