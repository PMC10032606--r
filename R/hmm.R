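# Diagonal-covariance Gaussian hidden Markov model fitted by Baum-Welch
# (scaled forward-backward EM), used to discretise dimerization trajectories
# into substate transition networks.

.hmm_emission_logdens <- function(x, means, vars) {
  # x: T x d; returns T x K log densities
  K <- nrow(means)
  sapply(seq_len(K), function(k)
    rowSums(stats::dnorm(x, mean = matrix(means[k, ], nrow(x), ncol(x),
                                          byrow = TRUE),
                         sd = matrix(sqrt(vars[k, ]), nrow(x), ncol(x),
                                     byrow = TRUE), log = TRUE)))
}

# scaled forward-backward for one sequence; returns gamma, xi-sums, loglik
.hmm_fb <- function(logB, A, p0) {
  Tn <- nrow(logB); K <- ncol(logB)
  B <- exp(logB - apply(logB, 1, max))
  off <- apply(logB, 1, max)
  alpha <- matrix(0, Tn, K); cvec <- numeric(Tn)
  alpha[1, ] <- p0 * B[1, ]
  cvec[1] <- sum(alpha[1, ]); alpha[1, ] <- alpha[1, ] / cvec[1]
  for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  for (t in (Tn - 1):1)
    beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  for (t in 1:(Tn - 1)) {
    m <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / cvec[t + 1]
    xi <- xi + m
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(off))
}

#' Fit a diagonal-Gaussian hidden Markov model
#'
#' Baum-Welch EM on one or more feature sequences.  Initialisation is k-means
#' on the pooled features with a sticky-diagonal transition guess; the
#' per-iteration log-likelihood is non-decreasing (up to numerical tolerance).
#'
#' @param X feature matrix (T x d) or list of matrices (one per trajectory).
#' @param n_states number of hidden states (>= 1).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed RNG seed (k-means initialisation).
#' @param var_floor variance floor per feature, guards degenerate emissions.
#' @return object of class `gaussian_hmm`: `transmat`, `means`, `vars`,
#'   `start`, `loglik` (trace), `converged`, `posteriors`.
#' @export
fit_gaussian_hmm <- function(X, n_states, max_iter = 200L, tol = 1e-7,
                             seed = 1L, var_floor = 1e-4) {
  if (is.matrix(X)) X <- list(X)
  X <- lapply(X, as.matrix)
  stopifnot(n_states >= 1)
  d <- ncol(X[[1]])
  pooled <- do.call(rbind, X)
  set.seed(seed)
  if (n_states == 1L) {
    means <- matrix(colMeans(pooled), 1)
    vars <- matrix(pmax(apply(pooled, 2, stats::var), var_floor), 1)
    logB <- .hmm_emission_logdens(pooled, means, vars)
    return(structure(list(transmat = matrix(1, 1, 1), means = means,
                          vars = vars, start = 1, loglik = sum(logB),
                          converged = TRUE,
                          posteriors = lapply(X, function(x)
                            matrix(1, nrow(x), 1))),
                     class = "gaussian_hmm"))
  }
  km <- stats::kmeans(pooled, centers = min(n_states, nrow(unique(pooled))),
                      nstart = 5, iter.max = 50)
  means <- km$centers
  if (nrow(means) < n_states)   # fewer distinct points than states
    means <- rbind(means, means[sample(nrow(means), n_states - nrow(means),
                                       replace = TRUE), , drop = FALSE] +
                     stats::rnorm((n_states - nrow(means)) * d, sd = 1e-3))
  gv <- pmax(apply(pooled, 2, stats::var), var_floor)
  vars <- matrix(gv, n_states, d, byrow = TRUE)
  A <- matrix(0.1 / (n_states - 1), n_states, n_states)
  diag(A) <- 0.9
  p0 <- rep(1 / n_states, n_states)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    stats_g <- lapply(X, function(x)
      .hmm_fb(.hmm_emission_logdens(x, means, vars), A, p0))
    ll <- sum(vapply(stats_g, `[[`, numeric(1), "loglik"))
    ll_trace <- c(ll_trace, ll)
    xi <- Reduce(`+`, lapply(stats_g, `[[`, "xi"))
    A <- xi / pmax(rowSums(xi), 1e-300)
    A[rowSums(xi) == 0, ] <- 1 / n_states
    p0 <- rowMeans(vapply(stats_g, function(s) s$gamma[1, ],
                          numeric(n_states)))
    G <- do.call(rbind, lapply(stats_g, `[[`, "gamma"))
    wk <- colSums(G)
    means <- (t(G) %*% pooled) / wk
    for (k in seq_len(n_states)) {
      dev2 <- sweep(pooled, 2, means[k, ])^2
      vars[k, ] <- pmax(colSums(G[, k] * dev2) / wk[k], var_floor)
    }
    if (it > 1 && abs(ll - ll_trace[it - 1]) <
        tol * (abs(ll_trace[it - 1]) + 1)) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations")
  post <- lapply(X, function(x)
    .hmm_fb(.hmm_emission_logdens(x, means, vars), A, p0)$gamma)
  structure(list(transmat = A, means = means, vars = vars, start = p0,
                 loglik = ll_trace, converged = converged,
                 posteriors = post),
            class = "gaussian_hmm")
}

#' Viterbi-free state path (posterior decoding)
#' @param hmm a `gaussian_hmm`.
#' @return list of integer state paths (argmax posterior per frame).
#' @export
hmm_state_paths <- function(hmm) {
  lapply(hmm$posteriors, function(g) max.col(g, ties.method = "first"))
}
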