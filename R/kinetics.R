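# Markov-chain kinetics: lag-time transition matrices and implied timescales,
# exact mean first-passage times by graph transformation (node elimination),
# and empirical first-passage statistics with jackknife errors and the
# log-time Gaussian / exponential diagnostics.

#' Row-stochastic transition matrix from a network
#'
#' `T_ij = n_ij / sum_j n_ij` from the symmetrised counts, so detailed balance
#' holds by construction and the spectrum is real.
#'
#' @param net a `transition_network` (or a raw count matrix).
#' @return object of class `transition_matrix`: `T`, `lag`, `lag_ps`, `pi`.
#' @export
transition_matrix <- function(net) {
  C <- if (inherits(net, "transition_network")) net$sym else as.matrix(net)
  rs <- rowSums(C)
  if (any(rs == 0))
    stop("state(s) with no outgoing counts: ",
         paste(which(rs == 0), collapse = ", "))
  T <- C / rs
  structure(list(T = T, lag = if (is.list(net)) net$lag else 1L,
                 lag_ps = if (is.list(net)) net$lag_ps else NULL,
                 pi = rs / sum(rs), sym = TRUE),
            class = "transition_matrix")
}

# Eigenvalues of a detailed-balance transition matrix via the symmetric
# similarity transform D^{1/2} T D^{-1/2}; falls back to the general solver.
.tm_eigen <- function(T, pi = NULL) {
  if (!is.null(pi) && all(pi > 0)) {
    s <- sqrt(pi)
    S <- (s %o% (1 / s)) * T
    Ssym <- (S + t(S)) / 2
    if (max(abs(S - Ssym)) < 1e-8) {
      ev <- eigen(Ssym, symmetric = TRUE, only.values = TRUE)$values
      return(ev[order(abs(ev), decreasing = TRUE)])
    }
  }
  ev <- eigen(T, only.values = TRUE)$values
  ev[order(Mod(ev), decreasing = TRUE)]
}

#' Implied relaxation timescales
#'
#' `t_i = -lag / log |lambda_i|` for the sub-dominant eigenvalues of the
#' lag-time transition matrix.  An eigenvalue of modulus 1 beyond the first
#' signals a disconnected chain and is reported as `Inf`; a zero eigenvalue
#' decays instantly (`t = 0`).
#'
#' @param tm a `transition_matrix` (or bare matrix).
#' @param lag lag time (frames or physical units; the timescales inherit this
#'   unit).
#' @return data frame with `eigenvalue` (modulus) and `timescale`, slowest
#'   first (dominant eigenvalue excluded).
#' @export
implied_timescales <- function(tm, lag = NULL) {
  if (inherits(tm, "transition_matrix")) {
    if (is.null(lag)) lag <- if (!is.null(tm$lag_ps)) tm$lag_ps else tm$lag
    ev <- .tm_eigen(tm$T, tm$pi)
  } else {
    if (is.null(lag)) lag <- 1
    ev <- .tm_eigen(as.matrix(tm))
  }
  m <- Mod(ev)
  if (abs(m[1] - 1) > 1e-8)
    warning("dominant eigenvalue differs from 1 by ", signif(m[1] - 1, 3))
  m <- m[-1]
  ts <- ifelse(m >= 1 - 1e-12, Inf, ifelse(m <= 0, 0, -lag / log(m)))
  data.frame(eigenvalue = m, timescale = ts)
}

#' Mean first-passage time by graph transformation
#'
#' Iteratively eliminates intermediate nodes, renormalising branching
#' probabilities and waiting times, which yields the exact MFPT of the
#' discrete chain (equal to the linear-system solution `(I - T_QQ) m = tau`
#' but numerically robust).  Elimination follows a minimum-degree heuristic;
#' the result is order independent.
#'
#' @param tm a `transition_matrix` or bare row-stochastic matrix.
#' @param source,target disjoint state index sets.
#' @param lag time per step (the MFPT inherits this unit); defaults to the
#'   matrix's physical lag when available.
#' @param weights optional source weighting for the aggregate MFPT (default:
#'   stationary weights restricted to the sources, else uniform).
#' @return list with `mfpt` (weighted aggregate), `per_source` (named vector)
#'   and `unit_lag`.
#' @export
mfpt_graph_transform <- function(tm, source, target, lag = NULL,
                                 weights = NULL) {
  if (inherits(tm, "transition_matrix")) {
    P <- tm$T
    if (is.null(lag)) lag <- if (!is.null(tm$lag_ps)) tm$lag_ps else tm$lag
    if (is.null(weights)) weights <- tm$pi[source]
  } else {
    P <- as.matrix(tm)
    if (is.null(lag)) lag <- 1
  }
  n <- nrow(P)
  source <- unique(as.integer(source)); target <- unique(as.integer(target))
  stopifnot(max(source, target) <= n, min(source, target) >= 1)
  if (length(intersect(source, target)) > 0)
    return(list(mfpt = 0, per_source = stats::setNames(
      rep(0, length(source)), source)[as.character(source)], unit_lag = lag))
  tau <- rep(as.numeric(lag), n)
  keep <- rep(TRUE, n)
  inter <- setdiff(seq_len(n), c(source, target))
  P[target, ] <- 0                      # absorbing targets
  while (length(inter) > 0L) {
    deg <- vapply(inter, function(x) sum(P[keep, x] > 0), numeric(1))
    x <- inter[which.min(deg)]
    px <- P[, x]; Pxx <- P[x, x]
    if (Pxx >= 1 - 1e-14) {
      # node is a trap disconnected from the targets
      P[, x] <- 0
    } else {
      fac <- 1 / (1 - Pxx)
      rows <- which(keep & px > 0 & seq_len(n) != x)
      if (length(rows) > 0L) {
        P[rows, ] <- P[rows, ] + (px[rows] * fac) %o% P[x, ]
        tau[rows] <- tau[rows] + px[rows] * fac * tau[x]
      }
      P[rows, x] <- 0
    }
    P[x, ] <- 0; P[, x] <- 0
    keep[x] <- FALSE
    inter <- setdiff(inter, x)
  }
  # remaining: sources (possibly inter-source transitions) + absorbing targets
  S <- source
  A <- P[S, S, drop = FALSE]
  reach <- rowSums(P[S, target, drop = FALSE])
  m <- tryCatch(solve(diag(length(S)) - A, tau[S]),
                error = function(e) rep(Inf, length(S)))
  # a source with no path to the target has all its mass absorbed elsewhere
  tot <- rowSums(A) + reach
  m[tot < 1e-10 & reach < 1e-12] <- Inf
  per <- stats::setNames(m, S)
  if (is.null(weights) || sum(weights) == 0) weights <- rep(1, length(S))
  list(mfpt = sum(per * weights) / sum(weights), per_source = per,
       unit_lag = lag)
}

#' First-passage statistics with jackknife errors
#'
#' Mean FPT over uncensored samples with the delete-one jackknife standard
#' error, a normalised histogram, a single-Gaussian fit to log-times (with a
#' Kolmogorov-Smirnov quality check that flags multimodal mixtures), and a
#' single-exponential diagnostic for Poissonian (two-state) kinetics.
#'
#' @param tau first-passage times (positive; any unit).
#' @param censored logical flags for trajectories that never arrived; these
#'   are excluded from the mean but counted in `censor_fraction`.
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @return list with `mean`, `se_jackknife`, `n`, `censor_fraction`, `hist`,
#'   `log_gaussian` (`meanlog`, `sdlog`, `ks_p`, `ok`) and `exponential`
#'   (`rate`, `ks_p`, `ok`).
#' @export
fpt_statistics <- function(tau, censored = rep(FALSE, length(tau)),
                           breaks = "Sturges") {
  stopifnot(length(tau) == length(censored))
  cf <- mean(censored)
  tau <- tau[!censored]
  if (length(tau) == 0L)
    return(list(mean = NA_real_, se_jackknife = NA_real_, n = 0L,
                censor_fraction = cf, hist = NULL, log_gaussian = NULL,
                exponential = NULL))
  stopifnot(all(tau > 0))
  if (length(tau) < 2L) stop("need at least 2 uncensored samples")
  n <- length(tau)
  mn <- mean(tau)
  loo <- (sum(tau) - tau) / (n - 1)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  h <- graphics::hist(tau, breaks = breaks, plot = FALSE)
  lt <- log(tau)
  ml <- mean(lt); sl <- stats::sd(lt)
  ks_g <- if (sl > 0)
    suppressWarnings(stats::ks.test(lt, "pnorm", ml, sl))$p.value else 1
  ks_e <- suppressWarnings(stats::ks.test(tau, "pexp", 1 / mn))$p.value
  list(mean = mn, se_jackknife = se, n = n, censor_fraction = cf, hist = h,
       log_gaussian = list(meanlog = ml, sdlog = sl, ks_p = ks_g,
                           ok = ks_g > 0.01),
       exponential = list(rate = 1 / mn, ks_p = ks_e, ok = ks_e > 0.01))
}

# Map a direction string "X->Y" onto the set of target labels.
.fpt_targets <- function(direction, labs) {
  parts <- strsplit(direction, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("direction must be of the form 'FROM->TO'")
  to <- trimws(parts[2])
  if (to == "N*") setdiff(labs, "RC")
  else if (to %in% c(labs, "RC")) to
  else stop("unknown target class: ", to)
}

#' First-passage times from labelled trajectories
#'
#' Classifies every saved frame against the fibril references and records, per
#' trajectory, the first time a frame of the target class is visited.
#' Trajectories that start in the target class are excluded (with a warning)
#' and counted; trajectories that never arrive are censored at their length.
#'
#' @param trajs list of trajectories (`sop_trajectory` or frame arrays).
#' @param refs list of [reference_structure()].
#' @param chi_c overlap threshold for the N* call.
#' @param direction transition, e.g. `"RC->N*"`, `"N*->RC"`,
#'   `"U-bend->S-bend"`; the right-hand side names the target class.
#' @param stride_ps physical time between saved frames (ps); taken from the
#'   trajectory when available.
#' @return object of class `fpt_sample`: data frame `tau` (ps), `censored`,
#'   plus attributes `n_degenerate` (start-in-target count) and `direction`.
#' @export
first_passage_from_trajectories <- function(trajs, refs, chi_c = 0.30,
                                            direction = "RC->N*",
                                            stride_ps = NULL) {
  if (!is.list(trajs) || inherits(trajs, "sop_trajectory")) trajs <- list(trajs)
  labs <- vapply(refs, function(r) r$label, character(1))
  targets <- .fpt_targets(direction, labs)
  out <- lapply(trajs, function(tr) {
    dt <- if (inherits(tr, "sop_trajectory")) tr$dt_save_ps else stride_ps
    if (is.null(dt)) stop("stride_ps required for bare frame arrays")
    fr <- trajectory_frames(tr)
    if (dim(fr)[1] < 2L) stop("trajectory shorter than one save stride")
    lab <- apply(fr, 1, function(x)
      as.character(classify_nstar(x, refs, chi_c)))
    hit <- which(lab %in% targets)
    if (length(hit) > 0 && hit[1] == 1L)
      return(data.frame(tau = 0, censored = FALSE, degenerate = TRUE))
    if (length(hit) == 0)
      data.frame(tau = (dim(fr)[1] - 1) * dt, censored = TRUE,
                 degenerate = FALSE)
    else
      data.frame(tau = (hit[1] - 1) * dt, censored = FALSE, degenerate = FALSE)
  })
  d <- do.call(rbind, out)
  ndeg <- sum(d$degenerate)
  if (ndeg > 0)
    warning(ndeg, " trajectorie(s) started in the target class; excluded")
  d <- d[!d$degenerate, c("tau", "censored")]
  structure(d, n_degenerate = ndeg, direction = direction,
            class = c("fpt_sample", "data.frame"))
}
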