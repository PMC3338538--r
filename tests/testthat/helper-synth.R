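# Shared fixture builders: small synthetic sessions generated in code.

# Small exploration session (6 blocks) extracted to a sample set.
small_exploration_samples <- function(seed = 1, n_voxels = 400,
                                      n_informative = 30, effect = 3,
                                      noise = list(white_sd = 1,
                                                   ar1_coef = 0.3,
                                                   drift_amp = 1,
                                                   motion_amp = 0.3),
                                      n_repetitions = 2) {
  ev <- make_exploration_design(n_repetitions = n_repetitions, seed = seed)
  pat <- make_activation_patterns(n_voxels, n_informative,
                                  effect_size = effect, seed = seed + 1)
  ns <- ceiling(max(ev$onset + ev$duration + 20) / 2.04)
  pp <- acq_params(n_scans = ns, n_voxels = n_voxels)
  sim <- simulate_bold(ev, pat, pp, noise = noise, seed = seed + 2)
  res <- if (all(unlist(noise) == 0)) sim$series else regress_confounds(sim)
  list(samples = extract_exploration_samples(res, ev, tr = 2.04),
       events = ev, patterns = pat, sim = sim, params = pp)
}

# Imagery session with category-dependent recall, extracted to samples.
small_imagery_samples <- function(seed = 1, n_voxels = 500,
                                  n_informative = 40, effect = 1.5,
                                  recall_prob = c(1, 0.65, 0.93)) {
  ev <- make_imagery_design(recall_prob = recall_prob, seed = seed)
  pat <- make_activation_patterns(n_voxels, n_informative,
                                  effect_size = effect, seed = seed + 1)
  ns <- ceiling(max(ev$onset + ev$duration + 20) / 2.04)
  pp <- acq_params(n_scans = ns, n_voxels = n_voxels)
  sim <- simulate_bold(ev, pat, pp,
                       noise = list(white_sd = 1, ar1_coef = 0.3,
                                    drift_amp = 1, motion_amp = 0.3),
                       seed = seed + 2)
  suppressMessages(
    list(samples = extract_imagery_samples(regress_confounds(sim), ev,
                                           tr = 2.04),
         events = ev))
}

# Direct sample-level generator (no BOLD forward model): gaussian class
# means on informative voxels. Fast fixture for classifier/wrapper tests.
gaussian_samples <- function(seed, n_per_class = 30, n_blocks = 3,
                             n_voxels = 100, n_informative = 10,
                             effect = 1) {
  set.seed(seed)
  n <- n_per_class * 3
  lab <- rep(categories(), each = n_per_class)
  blk <- rep(rep(seq_len(n_blocks), length.out = n_per_class), 3)
  X <- matrix(rnorm(n * n_voxels), n, n_voxels)
  for (ci in 1:3) {
    vox <- ((ci - 1) * n_informative + 1):(ci * n_informative)
    X[lab == categories()[ci], vox] <-
      X[lab == categories()[ci], vox] + effect
  }
  mvpadecode:::new_sample_set(X, lab, blk, vector("list", n))
}

# Dense-QP oracle for the SVM dual: SMO-style pairwise coordinate ascent,
# independent of LIBSVM. Maximizes sum(a) - 1/2 sum a_i a_j y_i y_j K_ij
# s.t. 0 <= a <= C, sum(a y) = 0.
svm_dual_oracle <- function(X, y, C = 1, iters = 200000, tol = 1e-12) {
  K <- tcrossprod(X)
  n <- length(y)
  a <- numeric(n)
  g <- rep(1, n)  # gradient of objective wrt a: 1 - (Q a)
  Q <- (y %o% y) * K
  for (it in seq_len(iters)) {
    # pick most violating pair
    up <- which((y > 0 & a < C) | (y < 0 & a > 0))
    dn <- which((y > 0 & a > 0) | (y < 0 & a < C))
    gy <- g * y
    i <- up[which.max(gy[up])]
    j <- dn[which.min(gy[dn])]
    if (gy[i] - gy[j] < tol) break
    eta <- Q[i, i] + Q[j, j] - 2 * y[i] * y[j] * Q[i, j]
    if (eta <= 0) eta <- 1e-12
    lam <- (gy[i] - gy[j]) / eta
    # box constraints along the feasible direction
    lam <- min(lam,
               if (y[i] > 0) C - a[i] else a[i],
               if (y[j] > 0) a[j] else C - a[j])
    a[i] <- a[i] + y[i] * lam
    a[j] <- a[j] - y[j] * lam
    # recompute gradient exactly (small n, exactness over speed)
    g <- 1 - drop(Q %*% a)
  }
  obj <- sum(a) - 0.5 * drop(a %*% Q %*% a)
  list(alpha = a, objective = obj)
}

# Gauss-Hermite nodes/weights via Golub-Welsch (eigen of the Jacobi
# matrix), for the GP marginal-likelihood quadrature oracle.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact log marginal likelihood of the probit GP by tensor-product
# Gauss-Hermite quadrature over the latent vector (n <= 3).
gp_logZ_quadrature <- function(K, y, n_nodes = 60) {
  n <- length(y)
  gh <- gauss_hermite(n_nodes)
  L <- t(chol(K + diag(1e-10, n)))
  grids <- do.call(expand.grid, rep(list(seq_len(n_nodes)), n))
  nodes <- matrix(gh$nodes[as.matrix(grids)], ncol = n)
  logw <- matrix(log(gh$weights)[as.matrix(grids)], ncol = n)
  f <- sqrt(2) * nodes %*% t(L)   # rows: latent draws f = L z sqrt(2)
  loglik <- rowSums(stats::pnorm(f * rep(y, each = nrow(f)), log.p = TRUE))
  tot <- rowSums(logw) + loglik - n / 2 * log(pi)
  m <- max(tot)
  m + log(sum(exp(tot - m)))
}
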