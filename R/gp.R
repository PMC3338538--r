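# Gaussian-process binary classification with an expectation-propagation
# (EP) posterior approximation, probit likelihood, and an inhomogeneous
# linear kernel. Written against the standard EP equations for GP
# classification (site updates by moment matching, marginal likelihood from
# the cavity/site decomposition).

#' Inhomogeneous linear kernel
#'
#' `K[i, j] = sigma^2 * <x1_i, x2_j> + sigma0sq`: a linear kernel whose
#' prior covariance is `sigma^2 I` with a bias term `sigma0sq`. Both terms
#' are tied to the single hyperparameter sigma by default
#' (`sigma0sq = sigma^2`).
#'
#' @param X1,X2 Matrices with matching feature dimension.
#' @param sigma Prior scale (> 0).
#' @param sigma0sq Bias variance (default `sigma^2`).
#' @return `nrow(X1)` x `nrow(X2)` kernel matrix.
#' @export
linear_kernel_inhom <- function(X1, X2, sigma = exp(1), sigma0sq = sigma^2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2))
    stop_invalid("feature dimensions differ: ", ncol(X1), " vs ", ncol(X2))
  if (sigma < 0) stop_invalid("`sigma` must be >= 0")
  sigma^2 * tcrossprod(X1, X2) + sigma0sq
}

#' Center a kernel matrix
#'
#' Double centering `K - rowmean - colmean + grandmean`. In
#' `"independent"` mode the named matrix is centered using its own row and
#' column means (training and test blocks are each centered independently;
#' equivalent to subtracting each block's own feature mean). In `"train"`
#' mode a rectangular test-vs-train block is centered using the training
#' kernel's statistics, the conventional choice; `K_train` (uncentered)
#' must then be supplied.
#'
#' @param K Square (train) or rectangular (test-vs-train) kernel matrix.
#' @param mode `"independent"` (default) or `"train"`.
#' @param K_train Uncentered training kernel, required for
#'   `mode = "train"` on rectangular input.
#' @return Centered matrix of the same shape.
#' @export
center_kernel <- function(K, mode = c("independent", "train"),
                          K_train = NULL) {
  mode <- match.arg(mode)
  K <- as.matrix(K)
  if (mode == "independent" || is.null(K_train)) {
    if (mode == "train" && is.null(K_train))
      stop_invalid("`K_train` required for mode = \"train\"")
    rm_ <- rowMeans(K); cm <- colMeans(K); gm <- mean(K)
    return(K - outer(rm_, rep(1, ncol(K))) -
             outer(rep(1, nrow(K)), cm) + gm)
  }
  n <- ncol(K)
  stopifnot(ncol(K_train) == n, nrow(K_train) == n)
  K - outer(rowMeans(K), rep(1, n)) -
    outer(rep(1, nrow(K)), colMeans(K_train)) + mean(K_train)
}

probit_ratio <- function(z) exp(stats::dnorm(z, log = TRUE) -
                                  stats::pnorm(z, log.p = TRUE))

ep_core <- function(K, y, tol = 1e-4, max_sweeps = 100, damping = 0.8) {
  n <- length(y)
  K <- K + diag(1e-8 * (1 + mean(diag(K))), n)
  tau <- numeric(n); nu <- numeric(n)
  Sigma <- K; mu <- numeric(n)
  delta <- Inf; sweeps <- 0
  eta <- damping
  while (sweeps < max_sweeps && delta > tol) {
    tau_old <- tau; nu_old <- nu
    for (i in seq_len(n)) {
      tau_mi <- 1 / Sigma[i, i] - tau[i]
      nu_mi <- mu[i] / Sigma[i, i] - nu[i]
      if (tau_mi <= 0) next  # skip pathological cavity
      mu_mi <- nu_mi / tau_mi; s2_mi <- 1 / tau_mi
      z <- y[i] * mu_mi / sqrt(1 + s2_mi)
      r <- probit_ratio(z)
      mu_hat <- mu_mi + y[i] * s2_mi * r / sqrt(1 + s2_mi)
      s2_hat <- s2_mi - s2_mi^2 * r * (z + r) / (1 + s2_mi)
      s2_hat <- max(s2_hat, 1e-10)
      # damped site update; damping stabilizes EP on large-scale kernels
      dtau <- eta * (1 / s2_hat - tau_mi - tau[i])
      dnu <- eta * (mu_hat / s2_hat - nu_mi - nu[i])
      if (!is.finite(dtau) || !is.finite(dnu)) next
      # keep site precisions nonnegative
      if (tau[i] + dtau < 0) dtau <- -tau[i]
      denom <- 1 + dtau * Sigma[i, i]
      if (abs(denom) < 1e-12) next
      tau[i] <- tau[i] + dtau
      nu[i] <- nu[i] + dnu
      si <- Sigma[, i]
      Sigma <- Sigma - (dtau / denom) * tcrossprod(si)
      mu <- drop(Sigma %*% nu)
    }
    # recompute Sigma, mu from scratch for numerical hygiene
    srt <- sqrt(pmax(tau, 0))
    B <- diag(n) + (srt %o% srt) * K
    U <- chol(B)
    V <- backsolve(U, srt * K, transpose = TRUE)  # U^-T (S^1/2 K)
    Sigma <- K - crossprod(V)
    mu <- drop(Sigma %*% nu)
    sweeps <- sweeps + 1
    delta <- max(abs(tau - tau_old), abs(nu - nu_old))
    if (any(!is.finite(tau)) || any(!is.finite(nu)))
      stop_invalid("EP diverged: non-finite site parameters at sweep ",
                   sweeps)
  }
  # cavity parameters at the fixed point
  d <- diag(Sigma)
  tau_mi <- pmax(1 / d - tau, 1e-12); nu_mi <- mu / d - nu
  mu_mi <- nu_mi / tau_mi; s2_mi <- 1 / tau_mi
  z <- y * mu_mi / sqrt(1 + s2_mi)
  # log marginal likelihood, in a form that stays finite as site
  # precisions tend to zero (no division by tau):
  #   logZ = sum log Phi(z_i)
  #        + 1/2 sum log(1 + tau_i * s2_mi) - sum log L_ii
  #        + 1/2 nu' Sigma nu
  #        + sum (tau_i mu_mi^2 - 2 mu_mi nu_i - s2_mi nu_i^2)
  #              / (2 (1 + tau_i s2_mi))
  srt <- sqrt(pmax(tau, 0))
  B <- diag(n) + (srt %o% srt) * K
  U <- chol(B)
  logZ <- sum(stats::pnorm(z, log.p = TRUE)) +
    0.5 * sum(log1p(tau * s2_mi)) - sum(log(diag(U))) +
    0.5 * sum(nu * drop(Sigma %*% nu)) +
    sum((tau * mu_mi^2 - 2 * mu_mi * nu - s2_mi * nu^2) /
          (2 * (1 + tau * s2_mi)))
  list(tau = tau, nu = nu, sweeps = sweeps, delta = delta,
       converged = delta <= tol, logZ = logZ)
}

#' Train a GP binary classifier by expectation propagation
#'
#' Probit-likelihood Gaussian-process classification over the centered
#' inhomogeneous linear kernel. EP iterates moment-matched site updates
#' until the largest site-parameter change falls below `tol` (default
#' 1e-4) or `max_sweeps` sweeps. The kernel scale sigma is initialized at
#' `log(sigma) = 1`; setting `optimize_sigma = TRUE` refines it by
#' maximizing the EP log marginal likelihood from that starting point (off
#' by default: after centering, sigma is a pure scale on a fixed kernel
#' and the refinement rarely changes class rankings).
#'
#' @param X Samples x features matrix.
#' @param y Labels: two-level factor (first level positive) or +/-1.
#' @param sigma Initial kernel scale (default `exp(1)`).
#' @param centering Kernel centering mode, `"independent"` (default) or
#'   `"train"`; see [center_kernel()].
#' @param optimize_sigma Refine sigma by EP marginal likelihood?
#' @param normalize Scale the centered training kernel to unit mean
#'   diagonal (default `TRUE`)? This trace normalization keeps the latent
#'   scale set by sigma independent of voxel count and signal units, the
#'   regime in which the probit likelihood is informative and EP is
#'   numerically well behaved.
#' @param tol,max_sweeps EP convergence controls.
#' @return A `gp_probit` object with site parameters `tau`/`nu`, the
#'   fitted `sigma`, `logZ` (approximate log marginal likelihood) and a
#'   `converged` flag.
#' @export
gp_ep_train <- function(X, y, sigma = exp(1),
                        centering = c("independent", "train"),
                        optimize_sigma = FALSE, normalize = TRUE,
                        tol = 1e-4, max_sweeps = 100) {
  centering <- match.arg(centering)
  X <- as.matrix(X)
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop_invalid("numeric labels must be -1/+1")
    lev <- c("+1", "-1"); ypm <- y
  } else {
    yf <- droplevels(as.factor(y)); lev <- levels(yf)
    if (nlevels(yf) != 2) stop_invalid("exactly two classes required")
    ypm <- ifelse(yf == lev[1], 1, -1)
  }
  # unit-sigma centered kernel; the bias term sigma0^2 is annihilated by
  # the centering, so sigma enters only as an overall scale
  K0 <- center_kernel(linear_kernel_inhom(X, X, sigma = 1, sigma0sq = 0),
                      mode = "independent")
  kscale <- if (normalize) mean(diag(K0)) else 1
  if (kscale <= 0) kscale <- 1
  kern <- function(s) (s^2 / kscale) * K0
  if (optimize_sigma) {
    obj <- function(ls) -ep_core(kern(exp(ls)), ypm, tol = tol,
                                 max_sweeps = max_sweeps)$logZ
    f_init <- obj(log(sigma))
    opt <- stats::optimize(obj, interval = c(log(sigma) - 3, log(sigma) + 3),
                           tol = 0.1)
    if (opt$objective < f_init) sigma <- exp(opt$minimum)
  }
  Kc <- kern(sigma)
  fit <- ep_core(Kc, ypm, tol = tol, max_sweeps = max_sweeps)
  structure(c(fit, list(X = X, y = ypm, sigma = sigma, kscale = kscale,
                        centering = centering, Kc = Kc, levels = lev)),
            class = "gp_probit")
}

#' @export
print.gp_probit <- function(x, ...) {
  cat(sprintf(paste0("<gp_probit: %d samples x %d features, sigma = %.3f,",
                     " %s after %d sweeps (max change %.2g)>\n"),
              nrow(x$X), ncol(x$X), x$sigma,
              if (x$converged) "converged" else "NOT converged",
              x$sweeps, x$delta))
  invisible(x)
}

#' Predictive class probabilities from an EP-trained GP
#'
#' Pushes the EP predictive latent mean and variance through the probit:
#' `p = Phi(mean / sqrt(1 + var))`, the probability of the positive (first
#' level) class. The test-vs-train kernel block is centered according to
#' the model's centering mode.
#'
#' @param model A `gp_probit`.
#' @param newdata Samples x features matrix.
#' @return Probabilities in (0, 1). A warning is attached if EP had not
#'   converged.
#' @export
gp_predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "gp_probit"))
  if (!model$converged)
    warning("EP had not converged; probabilities may be inaccurate")
  Xte <- as.matrix(newdata)
  sc <- model$sigma^2 / model$kscale
  Ks_raw <- linear_kernel_inhom(Xte, model$X, sigma = 1, sigma0sq = 0)
  Ktt_raw <- linear_kernel_inhom(Xte, Xte, sigma = 1, sigma0sq = 0)
  if (model$centering == "independent") {
    Ks <- sc * center_kernel(Ks_raw, mode = "independent")
    ktt <- sc * diag(center_kernel(Ktt_raw, mode = "independent"))
  } else {
    Ktr_raw <- linear_kernel_inhom(model$X, model$X, sigma = 1, sigma0sq = 0)
    Ks <- sc * center_kernel(Ks_raw, mode = "train", K_train = Ktr_raw)
    n <- nrow(model$X)
    ktt <- sc * (diag(Ktt_raw) - (2 / n) * rowSums(Ks_raw) + mean(Ktr_raw))
  }
  n <- length(model$y)
  srt <- sqrt(pmax(model$tau, 0))
  B <- diag(n) + (srt %o% srt) * model$Kc
  U <- chol(B)
  w <- srt * backsolve(U, backsolve(U, srt * drop(model$Kc %*% model$nu),
                                    transpose = TRUE))
  mean_star <- drop(Ks %*% (model$nu - w))
  V <- backsolve(U, srt * t(Ks), transpose = TRUE)  # U^-T S^1/2 k*, per test col
  var_star <- pmax(ktt - colSums(V^2), 1e-12)
  p <- stats::pnorm(mean_star / sqrt(1 + var_star))
  pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps)
}
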