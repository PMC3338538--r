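test_that("inhomogeneous linear kernel matches the double-loop oracle", {
  set.seed(1)
  X1 <- matrix(rnorm(15), 5, 3); X2 <- matrix(rnorm(9), 3, 3)
  K <- linear_kernel_inhom(X1, X2, sigma = 1.7, sigma0sq = 0.4)
  for (i in 1:5) for (j in 1:3)
    expect_equal(K[i, j], 1.7^2 * sum(X1[i, ] * X2[j, ]) + 0.4,
                 tolerance = 1e-12)
  # orthonormal rows, sigma 1, no bias -> identity
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(linear_kernel_inhom(t(Q) , t(Q), sigma = 1, sigma0sq = 0),
               diag(4), tolerance = 1e-12)
  # sigma 0 -> constant bias matrix
  expect_equal(linear_kernel_inhom(X1, X2, sigma = 0, sigma0sq = 2),
               matrix(2, 5, 3), tolerance = 1e-12)
  expect_error(linear_kernel_inhom(X1, matrix(0, 2, 2)), "dimension")
})

test_that("kernel centering equals the projection-matrix oracle", {
  set.seed(2)
  X <- matrix(rnorm(20), 5, 4)
  K <- tcrossprod(X)
  H <- diag(5) - matrix(1 / 5, 5, 5)
  expect_equal(center_kernel(K), H %*% K %*% H, tolerance = 1e-12)
  Kc <- center_kernel(K)
  expect_lt(max(abs(rowMeans(Kc))), 1e-10)
  expect_lt(max(abs(colMeans(Kc))), 1e-10)
  # idempotent
  expect_equal(center_kernel(Kc), Kc, tolerance = 1e-10)
  # rectangular block, independent mode: H_m K H_n
  Xte <- matrix(rnorm(12), 3, 4)
  Kr <- tcrossprod(Xte, X)
  Hm <- diag(3) - matrix(1 / 3, 3, 3)
  expect_equal(center_kernel(Kr), Hm %*% Kr %*% H, tolerance = 1e-12)
  # train mode equals centering features by the training mean
  Kt <- center_kernel(Kr, mode = "train", K_train = K)
  Xc_tr <- scale(X, scale = FALSE)
  Xte_c <- sweep(Xte, 2, colMeans(X))
  expect_equal(Kt, tcrossprod(Xte_c, Xc_tr), tolerance = 1e-10)
})

test_that("SVM solves the symmetric two-point problem exactly", {
  X <- matrix(c(-1, 1), 2, 1)
  fit <- train_linear_svm(X, c(-1, 1), C = 1)
  expect_setequal(fit$index, 1:2)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(unname(predict(fit, matrix(c(-0.5, 0.5), 2, 1))), c(-1, 1))
  # boundary point maps to +1 by convention
  expect_equal(unname(predict(fit, matrix(0, 1, 1))), 1)
  expect_error(train_linear_svm(X, c(1, 1)), "two classes")
})

test_that("SVM dual matches the dense QP oracle and satisfies KKT", {
  for (s in 1:4) {
    set.seed(s)
    X <- matrix(rnorm(12), 6, 2)
    y <- c(1, 1, 1, -1, -1, -1)
    fit <- train_linear_svm(X, y, C = 1)
    ora <- svm_dual_oracle(X, y, C = 1)
    expect_lt(abs(fit$objective - ora$objective), 1e-6)
    # dual feasibility
    expect_true(all(fit$alpha > 0 & fit$alpha <= 1 + 1e-8))
    expect_lt(abs(sum(fit$alpha * fit$sv_y)), 1e-6)
    # KKT: non-SV training points have margin >= 1; bounded SVs <= 1
    f <- predict(fit, X, type = "decision")
    marg <- y * f
    non_sv <- setdiff(seq_len(6), fit$index)
    if (length(non_sv)) expect_true(all(marg[non_sv] >= 1 - 1e-6))
    at_bound <- fit$index[fit$alpha > 1 - 1e-8]
    if (length(at_bound)) expect_true(all(marg[at_bound] <= 1 + 1e-6))
  }
})

test_that("duplicating the training set leaves the decision unchanged", {
  # separable with margin so no dual coefficient sits at the C bound
  # (duplication relaxes the box constraint for bounded points)
  set.seed(5)
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c(1, -1), 5)
  X[, 1] <- X[, 1] * 0.2 + 3 * y
  f1 <- train_linear_svm(X, y)
  expect_true(all(f1$alpha < 1 - 1e-6))
  f2 <- train_linear_svm(rbind(X, X), c(y, y))
  Xn <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(f1, Xn, type = "decision"),
               predict(f2, Xn, type = "decision"), tolerance = 1e-4)
})

test_that("decision values agree with an explicit w.x + b loop", {
  set.seed(6)
  X <- matrix(rnorm(30), 15, 2)
  y <- rep(c(1, -1), length.out = 15)
  X[y == 1, ] <- X[y == 1, ] + 1.5
  fit <- train_linear_svm(X, y)
  f <- predict(fit, X, type = "decision")
  for (i in 1:15)
    expect_equal(f[i], sum(fit$w * X[i, ]) + fit$b, tolerance = 1e-12)
  expect_true(all(predict(fit, X) == ifelse(f >= 0, 1, -1)))
})

test_that("support-vector proportions sum to one and mirror imbalance", {
  X <- matrix(c(-2, -1.8, 2, 1.8), 4, 1)
  fit <- train_linear_svm(X, c(-1, -1, 1, 1))
  pr <- sv_class_proportions(fit)
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr), c(0.5, 0.5))
  # imbalanced data (3:1): minority class is over-represented among SVs
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n1 <- 60; n2 <- 20
    Xi <- rbind(matrix(rnorm(n1 * 5), n1, 5),
                matrix(rnorm(n2 * 5, mean = 0.8), n2, 5))
    yi <- c(rep(1, n1), rep(-1, n2))
    fi <- train_linear_svm(Xi, yi)
    pri <- sv_class_proportions(fi)
    if (pri[2] > n2 / (n1 + n2)) hits <- hits + 1
  }
  expect_gte(hits, 16)  # >= 80% of runs
})

test_that("EP respects the symmetry of mirror-image training points", {
  X <- matrix(c(-1, 1), 2, 1)
  fit <- gp_ep_train(X, c(-1, 1))
  expect_true(fit$converged)
  # symmetric test block (independent centering preserves the origin)
  p0 <- gp_predict_prob(fit, matrix(c(0, 0.7, -0.7), 3, 1))
  expect_equal(p0[1], 0.5, tolerance = 1e-6)
  expect_gt(p0[2], 0.5)
  expect_lt(p0[3], 0.5)
})

test_that("flipping labels flips GP probabilities", {
  set.seed(7)
  X <- matrix(rnorm(16), 8, 2)
  y <- rep(c(1, -1), 4)
  Xte <- matrix(rnorm(10), 5, 2)
  p1 <- gp_predict_prob(gp_ep_train(X, y), Xte)
  p2 <- gp_predict_prob(gp_ep_train(X, -y), Xte)
  expect_equal(p1, 1 - p2, tolerance = 1e-4)
})

test_that("EP log marginal likelihood matches quadrature on tiny data", {
  cases <- list(
    list(X = matrix(c(-1.2, 0.3, 1.5), 3, 1), y = c(-1, -1, 1)),
    list(X = matrix(c(-0.5, 0.1, 0.9), 3, 1), y = c(-1, 1, 1)),
    list(X = matrix(c(-2, 1), 2, 1), y = c(-1, 1)))
  for (cs in cases) {
    fit <- gp_ep_train(cs$X, cs$y)
    expect_true(fit$converged)
    lZ_oracle <- gp_logZ_quadrature(fit$Kc, cs$y)
    expect_lt(abs(fit$logZ - lZ_oracle), 0.05)
  }
})

test_that("EP site precisions are nonnegative and predictions well formed", {
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2)
  y <- ifelse(X[, 1] + 0.3 * rnorm(30) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  fit <- gp_ep_train(X, y)
  expect_true(all(fit$tau >= 0))
  p <- gp_predict_prob(fit, matrix(rnorm(40), 20, 2))
  expect_true(all(p > 0 & p < 1))
})

test_that("a far test point on the positive side gets probability > 0.95", {
  set.seed(9)
  n <- 30
  X <- rbind(matrix(rnorm(n * 3, mean = 2, sd = 0.3), n, 3),
             matrix(rnorm(n * 3, mean = -2, sd = 0.3), n, 3))
  y <- c(rep(1, n), rep(-1, n))
  fit <- gp_ep_train(X, y)
  # several test points, one far positive (independent centering needs
  # a non-degenerate test block)
  Xte <- rbind(matrix(5, 1, 3), matrix(-5, 1, 3),
               matrix(rnorm(6, sd = 0.2), 2, 3))
  p <- gp_predict_prob(fit, Xte)
  expect_gt(p[1], 0.95)
  expect_lt(p[2], 0.05)
})

test_that("both classifiers separate strongly informative samples", {
  ss <- gaussian_samples(10, n_per_class = 30, n_blocks = 3,
                         n_voxels = 50, n_informative = 10, effect = 2)
  tr <- ss$block != 3; te <- !tr
  keep <- ss$labels %in% c("faces", "animals")
  y <- factor(as.character(ss$labels[keep & tr]),
              levels = c("faces", "animals"))
  Xtr <- ss$X[keep & tr, ]; Xte <- ss$X[keep & te, ]
  truth <- ifelse(ss$labels[keep & te] == "faces", 1, -1)
  svm_acc <- mean(predict(train_linear_svm(Xtr, y), Xte) == truth)
  gp <- gp_ep_train(Xtr, y)
  gp_acc <- mean(ifelse(gp_predict_prob(gp, Xte) > 0.5, 1, -1) == truth)
  expect_gte(svm_acc, 0.95)
  expect_gte(gp_acc, 0.95)
})

test_that("sigma optimization improves or matches the EP marginal", {
  set.seed(11)
  X <- matrix(rnorm(30), 15, 2)
  y <- ifelse(X[, 1] > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  f0 <- gp_ep_train(X, y)
  f1 <- gp_ep_train(X, y, optimize_sigma = TRUE)
  expect_gte(f1$logZ, f0$logZ - 1e-6)
})
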