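# Overdamped Brownian dynamics (Ermak-McCammon) with optional hydrodynamic
# interactions via the Rotne-Prager-Yamakawa mobility tensor (with the
# overlap-regularised form below bead contact).  Physical-time bookkeeping is
# in units of the high-friction natural time tau_HF = gamma a^2 / E.

#' Natural Brownian time unit
#'
#' `tau_HF = gamma a^2 / E`, the time for a bead with friction `gamma` to
#' diffuse its own length scale `a` against the energy scale `E`.  Unit-system
#' agnostic: pass consistent units and get the time in those units.  With the
#' package defaults (gamma from eta = 1e-3 Pa s and the pinned hydrodynamic
#' radius, a = 1 Angstrom, E = 1 kcal/mol) this is 13.2 ps.
#'
#' @param gamma friction coefficient.
#' @param a length scale.
#' @param energy_scale energy scale.
#' @return tau_HF.
#' @export
natural_time_unit <- function(gamma, a, energy_scale) {
  if (any(c(gamma, a, energy_scale) <= 0)) stop("inputs must be positive")
  gamma * a^2 / energy_scale
}

#' Per-bead friction coefficient from Stokes' law
#'
#' @param eta solvent viscosity in Pa s.
#' @param a_h hydrodynamic bead radius in Angstrom.
#' @return gamma in kcal mol^-1 ps Angstrom^-2.
#' @export
friction_coefficient <- function(eta = 1e-3, a_h = 4.86538) {
  stopifnot(eta > 0, a_h > 0)
  6 * pi * eta * (a_h * 1e-10) * .GAMMA_CONV
}

#' Integrator configuration
#'
#' @param n_steps number of BD steps.
#' @param dt time step in units of tau_HF (default 0.05).
#' @param temperature temperature in K.
#' @param eta solvent viscosity, Pa s.
#' @param a_h hydrodynamic bead radius, Angstrom; the default reproduces
#'   tau_HF = 13.2 ps.
#' @param hydrodynamics `"none"` (free draining) or `"rpy"`.
#' @param save_stride save every this many steps.
#' @param seed RNG seed recorded in the trajectory metadata.
#' @param drift_cap maximum deterministic per-bead displacement per step,
#'   Angstrom; the drift is rescaled when a transient clash would exceed it
#'   (`Inf` disables).  Forces in thermally relevant regions stay far below
#'   the cap, so equilibrium sampling is unaffected.
#' @return object of class `bd_config` with the derived quantities `gamma`
#'   (kcal/mol/A^2 * ps), `tau_hf_ps`, `dt_ps`, `kBT` and `duration_ps`.
#' @export
bd_config <- function(n_steps, dt = 0.05, temperature = 298, eta = 1e-3,
                      a_h = 4.86538, hydrodynamics = c("none", "rpy"),
                      save_stride = 100L, seed = 1L, drift_cap = 0.5) {
  hydrodynamics <- match.arg(hydrodynamics)
  stopifnot(n_steps >= 0, dt > 0, temperature > 0, save_stride >= 1,
            drift_cap > 0)
  gamma <- friction_coefficient(eta, a_h)
  tau <- natural_time_unit(gamma, 1, 1)      # ps, at E = 1 kcal/mol, a = 1 A
  cfg <- list(n_steps = as.numeric(n_steps), dt = dt,
              temperature = temperature, eta = eta, a_h = a_h,
              hydrodynamics = hydrodynamics,
              save_stride = as.integer(save_stride), seed = as.integer(seed),
              drift_cap = drift_cap,
              gamma = gamma, tau_hf_ps = tau, dt_ps = dt * tau,
              kBT = thermal_energy(temperature),
              duration_ps = as.numeric(n_steps) * dt * tau)
  class(cfg) <- "bd_config"
  cfg
}

#' @export
print.bd_config <- function(x, ...) {
  cat(sprintf(paste0("bd_config: %g steps, dt = %g tau_HF (tau_HF = %.4g ps),",
                     " T = %g K, HI = %s\n  physical duration = %.4g ps",
                     " (%.3g microseconds)\n"),
              x$n_steps, x$dt, x$tau_hf_ps, x$temperature, x$hydrodynamics,
              x$duration_ps, x$duration_ps * 1e-6))
  invisible(x)
}

#' Rotne-Prager-Yamakawa mobility matrix
#'
#' Pairwise far-field mobility with the overlap-regularised form for bead
#' separations below `2 a_h`, so the tensor stays positive definite for every
#' configuration.  Units: Angstrom^2 / ps per (kcal/mol/Angstrom).
#'
#' @param coords n x 3 coordinate matrix.
#' @param a_h hydrodynamic bead radius, Angstrom.
#' @param gamma per-bead friction (from [friction_coefficient()]).
#' @return 3n x 3n mobility matrix (coordinate order x1,y1,z1,x2,...).
#' @export
rpy_mobility <- function(coords, a_h, gamma) {
  n <- nrow(coords)
  mu0 <- 1 / gamma
  mu <- diag(mu0, 3 * n)
  if (n == 1L) return(mu)
  a <- a_h
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- coords[i, ] - coords[j, ]
    r <- sqrt(sum(d^2))
    rh <- d / r
    P <- tcrossprod(rh)
    blk <- if (r >= 2 * a) {
      mu0 * (3 * a / (4 * r)) *
        ((1 + 2 * a^2 / (3 * r^2)) * diag(3) + (1 - 2 * a^2 / r^2) * P)
    } else {
      mu0 * ((1 - 9 * r / (32 * a)) * diag(3) + (3 * r / (32 * a)) * P)
    }
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    mu[ii, jj] <- blk
    mu[jj, ii] <- blk
  }
  mu
}

# One integration step.  `forces` is the current force matrix; returns the
# displaced coordinates.  Free draining:
#   dq = (dt/gamma) F + N(0, 2 kBT dt / gamma)   per coordinate.
# Hydrodynamic:
#   dq = dt mu F + sqrt(2 kBT dt) L z,   L t(L) = mu  (dense Cholesky).
# rescale the drift if any bead would move further than the cap (transient
# clashes only; thermally relevant forces never get close)
.cap_drift <- function(drift, cap) {
  if (!is.finite(cap)) return(drift)
  mx <- sqrt(max(rowSums(drift^2)))
  if (mx > cap) drift * (cap / mx) else drift
}

.bd_kernel_free <- function(coords, forces, dt_ps, gamma, kBT, cap = Inf) {
  coords + .cap_drift((dt_ps / gamma) * forces, cap) +
    matrix(stats::rnorm(length(coords), sd = sqrt(2 * kBT * dt_ps / gamma)),
           nrow(coords), 3)
}

.bd_kernel_rpy <- function(coords, forces, dt_ps, kBT, mu, cap = Inf) {
  L <- tryCatch(t(chol(mu)), error = function(e)
    stop("mobility matrix factorization failed (not positive definite); ",
         "configuration range: [", paste(signif(range(coords), 4),
         collapse = ", "), "]", call. = FALSE))
  fv <- as.vector(t(forces))
  drift <- matrix(dt_ps * (mu %*% fv), nrow(coords), 3, byrow = TRUE)
  noise <- sqrt(2 * kBT * dt_ps) * (L %*% stats::rnorm(length(fv)))
  coords + .cap_drift(drift, cap) +
    matrix(noise, nrow(coords), 3, byrow = TRUE)
}

#' Single free-draining BD step
#'
#' @param conf coordinate matrix.
#' @param topo,ff topology and force field (or supply `force_fn`).
#' @param cfg a [bd_config()].
#' @param force_fn optional function(coords) -> force matrix replacing the
#'   SOP-IDP forces (used for toy potentials and restrained systems).
#' @param sys optional precomputed [sop_system()].
#' @return displaced coordinate matrix.
#' @export
step_free_draining <- function(conf, topo = NULL, ff = NULL, cfg,
                               force_fn = NULL, sys = NULL) {
  if (is.null(force_fn)) {
    if (is.null(sys)) sys <- sop_system(topo, ff)
    force_fn <- function(x) .sop_eval(x, sys, want_forces = TRUE)$forces
  }
  .bd_kernel_free(conf, force_fn(conf), cfg$dt_ps, cfg$gamma, cfg$kBT,
                  cfg$drift_cap)
}

#' Single BD step with hydrodynamic interactions
#'
#' @inheritParams step_free_draining
#' @return displaced coordinate matrix.
#' @export
step_hydrodynamic <- function(conf, topo = NULL, ff = NULL, cfg,
                              force_fn = NULL, sys = NULL) {
  if (is.null(force_fn)) {
    if (is.null(sys)) sys <- sop_system(topo, ff)
    force_fn <- function(x) .sop_eval(x, sys, want_forces = TRUE)$forces
  }
  mu <- rpy_mobility(conf, cfg$a_h, cfg$gamma)
  .bd_kernel_rpy(conf, force_fn(conf), cfg$dt_ps, cfg$kBT, mu,
                 cfg$drift_cap)
}

# Bond-validity check used for the bounded overstretch retry.  Steps are
# rejected already at 0.9 R0: the Boltzmann weight there is negligible
# (U > 60 kcal/mol) but the near-singular FENE force would make the next
# step overshoot, so the integrator never enters that region.
.bonds_ok <- function(coords, sys, margin = 0.9) {
  if (is.null(sys)) return(TRUE)
  dxb <- coords[sys$bonds$i, , drop = FALSE] - coords[sys$bonds$j, , drop = FALSE]
  all(abs(sqrt(rowSums(dxb^2)) - sys$bonds$r0) < margin * sys$fene_R0)
}

#' Propagate a Brownian-dynamics trajectory
#'
#' Integrates `cfg$n_steps` steps from `initial`, saving every
#' `cfg$save_stride`-th frame (frame 1 is the initial condition).  A step that
#' overstretches a FENE bond is retried with a halved time step (fresh noise)
#' up to 8 times before failing; each event is counted in the metadata.
#' Identical config + initial conformation give bit-identical trajectories
#' (the seed is set at entry).
#'
#' @inheritParams step_free_draining
#' @param initial starting coordinate matrix.
#' @param sys optional precomputed [sop_system()]; with a custom `force_fn`
#'   it is still used for the bond-validity retry check.
#' @return object of class `sop_trajectory`: `frames` (n_frames x n_beads x 3
#'   array), `dt_save_ps`, `duration_ps`, `cfg`, `n_retries`.
#' @export
run_trajectory <- function(initial, topo = NULL, ff = NULL, cfg,
                           force_fn = NULL, sys = NULL) {
  if (is.null(force_fn)) {
    if (is.null(sys)) sys <- sop_system(topo, ff)
    force_fn <- function(x) .sop_eval(x, sys, want_forces = TRUE)$forces
  }
  set.seed(cfg$seed)
  hi <- cfg$hydrodynamics == "rpy"
  n_steps <- cfg$n_steps
  stride <- cfg$save_stride
  n_save <- if (n_steps == 0) 0L else floor(n_steps / stride)
  frames <- array(NA_real_, c(n_save + 1L, nrow(initial), 3L))
  frames[1L, , ] <- initial
  coords <- initial
  retries <- 0L
  step <- 0
  while (step < n_steps) {
    F <- force_fn(coords)
    dt_try <- cfg$dt_ps
    ok <- FALSE
    for (attempt in 0:8) {
      cap_try <- cfg$drift_cap * dt_try / cfg$dt_ps
      cand <- if (hi) {
        mu <- rpy_mobility(coords, cfg$a_h, cfg$gamma)
        .bd_kernel_rpy(coords, F, dt_try, cfg$kBT, mu, cap_try)
      } else {
        .bd_kernel_free(coords, F, dt_try, cfg$gamma, cfg$kBT, cap_try)
      }
      if (.bonds_ok(cand, sys)) { ok <- TRUE; break }
      retries <- retries + 1L
      dt_try <- dt_try / 2
    }
    if (!ok) stop("FENE bond overstretched after 8 step-halving retries at step ",
                  step + 1)
    coords <- cand
    step <- step + 1
    if (step %% stride == 0) frames[step / stride + 1L, , ] <- coords
  }
  structure(list(frames = frames, dt_save_ps = stride * cfg$dt_ps,
                 duration_ps = cfg$duration_ps, cfg = cfg,
                 n_retries = retries),
            class = "sop_trajectory")
}

#' @export
print.sop_trajectory <- function(x, ...) {
  cat(sprintf(paste0("sop_trajectory: %d frames x %d beads, frame spacing",
                     " %.4g ps, duration %.4g ps (%.3g microseconds)\n"),
              dim(x$frames)[1], dim(x$frames)[2], x$dt_save_ps,
              x$duration_ps, x$duration_ps * 1e-6))
  invisible(x)
}

#' Extract trajectory frames
#' @param traj an `sop_trajectory` (or a bare frames array).
#' @return n_frames x n_beads x 3 array.
#' @export
trajectory_frames <- function(traj) {
  if (inherits(traj, "sop_trajectory")) traj$frames
  else if (inherits(traj, "dimer_trajectory")) traj$traj$frames
  else traj
}
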