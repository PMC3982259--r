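test_that("gram matrix: rbf diagonal, linear form, and the tau^2 heuristic", {
  X <- rbind(c(1, 2), c(3, 0), c(0, 1))
  expect_equal(gramMatrix(X, spec = kernelSpec("linear")), tcrossprod(X))
  sp <- kernelSpec("rbf", sigma = 2)
  K <- gramMatrix(X, spec = sp)
  expect_equal(diag(K), rep(1, 3))     # K(u, u) = 1
  expect_equal(K[1, 2], exp(-sum((X[1, ] - X[2, ])^2) / 2), tolerance = 1e-12)
  # tau^2 = mean squared row norm: (5 + 9 + 1)/3
  expect_equal(tauSquared(X), 5)
  expect_equal(sigmaGrid(X), 5 * 2^(-4:4))
  expect_equal(tauSquared(X, squared = FALSE),
               mean(sqrt(c(5, 9, 1))), tolerance = 1e-12)
})

test_that("Q reduces to K when eta = 0 or classes are degenerate, and matches dense assembly", {
  ds <- randomDataset(61, nPos = 4, nNeg = 3, dim = 2)
  y <- classLabels(ds)
  K <- gramMatrix(features(ds), spec = kernelSpec("rbf", sigma = 1.7))
  expect_equal(assembleQ(K, y, eta = 0), K)
  g <- kernelWithinClassGraph(K, y, k = 2, t = 1)
  Q <- assembleQ(K, y, g, eta = 0.7)
  Ts <- scatterKernel(K, y, g)
  expect_equal(Q, K + 0.7 * (Ts$T1 + Ts$T2), tolerance = 1e-12)
  expect_true(isSymmetric(Q))
  # identical class members: locality terms vanish
  X2 <- rbind(c(0, 0), c(0, 0), c(3, 3), c(3, 3))
  K2 <- gramMatrix(X2, spec = kernelSpec("rbf", sigma = 1))
  g2 <- kernelWithinClassGraph(K2, c(1, 1, -1, -1), k = 1, t = 1)
  expect_equal(assembleQ(K2, c(1, 1, -1, -1), g2, eta = 3), K2, tolerance = 1e-12)
})

test_that("M is symmetric PSD and simplifies for the linear kernel at eta = 0", {
  ds <- randomDataset(62, nPos = 3, nNeg = 2, dim = 4)  # N < n: K invertible
  X <- features(ds)
  y <- classLabels(ds)
  K <- tcrossprod(X)
  M <- assembleM(K, y, assembleQ(K, y, eta = 0))
  # M = Y K' K^{-1} K Y = Y K Y
  expect_equal(M, K * tcrossprod(y), tolerance = 1e-6 * max(abs(K)),
               ignore_attr = TRUE)
  # random rbf instances: Theorem-type PSD bound
  for (seed in 1:5) {
    dsr <- randomDataset(seed + 400, nPos = 4, nNeg = 3, dim = 2)
    Kr <- gramMatrix(features(dsr), spec = kernelSpec("rbf", sigma = 0.9))
    gr <- kernelWithinClassGraph(Kr, classLabels(dsr), k = 2, t = 2)
    Mr <- assembleM(Kr, classLabels(dsr), assembleQ(Kr, classLabels(dsr), gr, 1.2))
    expect_true(isSymmetric(Mr))
    ev <- eigen(Mr, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
})

test_that("kernel dual objective matches the independent FISTA oracle", {
  for (seed in 1:4) {
    ds <- randomDataset(seed + 500, nPos = 5, nNeg = 4, dim = 2, sep = 1)
    y <- classLabels(ds)
    K <- gramMatrix(features(ds), spec = kernelSpec("rbf", sigma = 1.5))
    mu <- kernelMembership(K, y, "exponential", lambda = 0.5)
    g <- kernelWithinClassGraph(K, y, k = 2, t = 1)
    M <- assembleM(K, y, assembleQ(K, y, g, 0.8))
    ub <- c(mu[1:5] / (0.1 * 5), mu[6:9] / (0.1 * 4))
    nu <- 0.4 * min(sum(ub[1:5]), sum(ub[6:9]))
    dp <- new("CipDual", H = M, ub = ub, nu = nu, m1 = 5L)
    sol <- solveDual(dp)
    orc <- oracleDualQP(M, ub, nu, 5L)
    expect_lt(abs(sol$objective - orc$objective) / max(abs(orc$objective), 1e-10),
              1e-6)
  }
})

test_that("linear-kernel fit with eta = 0 reproduces the linear fit exactly", {
  for (seed in 1:6) {
    ds <- randomDataset(seed + 600, nPos = sample(4:10, 1), nNeg = sample(3:8, 1),
                        dim = 3, sep = 1.5)
    mu <- linearMembership(ds)
    ctl <- feasibleControl(ds, mu, frac = 0.4, eta = 0)
    lf <- fitLinearCip(ds, ctl, mu = mu)
    kf <- fitKernelCip(ds, ctl, kernelSpec("linear"), mu = mu)
    Xte <- matrix(rnorm(15), 5, 3)
    expect_equal(decisionValues(kf, features(ds)),
                 decisionValues(lf, features(ds)), tolerance = 1e-6)
    expect_equal(decisionValues(kf, Xte), decisionValues(lf, Xte),
                 tolerance = 1e-6)
    expect_equal(kf@bStar, lf@bStar, tolerance = 1e-6)
    expect_equal(kf@rhoStar, lf@rhoStar, tolerance = 1e-6)
    expect_identical(kf@variant, "noY")
  }
})

test_that("the doubled-label threshold variant breaks the linear reduction", {
  ds <- randomDataset(617, nPos = 6, nNeg = 4, dim = 2, sep = 2)
  mu <- linearMembership(ds)
  ctl <- feasibleControl(ds, mu, frac = 0.4, eta = 0)
  lf <- fitLinearCip(ds, ctl, mu = mu)
  kfY <- fitKernelCip(ds, ctl, kernelSpec("linear"), mu = mu,
                      variant = "asPrinted")
  expect_identical(kfY@variant, "asPrinted")
  expect_gt(max(abs(decisionValues(kfY, features(ds)) -
                    decisionValues(lf, features(ds)))), 1e-3)
})

test_that("representer expansion reproduces training decision values two ways", {
  ds <- randomDataset(63, nPos = 6, nNeg = 4, dim = 2)
  y <- classLabels(ds)
  ctl <- cipControl(nu = 2, v1 = 0.1, v2 = 0.1, eta = 0.5, k = 2, t = 1,
                    family = "exponential", lambda = 0.3)
  kf <- fitKernelCip(ds, ctl)
  K <- gramMatrix(features(ds), spec = kernelSpec("rbf", sigma = kf@kernel$sigma))
  # via beta on K
  f1 <- as.numeric(K %*% kf@beta)
  # via alpha through the defining algebra: K beta = K Q^{-1} K Y alpha,
  # and y * (M alpha) = y * (Y K Q^{-1} K Y alpha) = K Q^{-1} K Y alpha
  g <- kernelWithinClassGraph(K, y, ctl$k, ctl$t)
  M <- assembleM(K, y, assembleQ(K, y, g, ctl$eta), check = FALSE)
  f2 <- y * as.numeric(M %*% kf@alpha)
  expect_equal(f1, f2, tolerance = 1e-6)
  # duplicating a training point reproduces its decision value
  expect_equal(decisionValues(kf, features(ds)[3, , drop = FALSE]),
               f1[3] + kf@bStar, tolerance = 1e-8)
})

test_that("rbf kernel separates the interleaved-arcs pattern", {
  ds <- simulateDataset(simSpec(nPos = 40, nNeg = 20, dim = 2, separation = 2,
                                shape = "two_arcs", seed = 5))
  ctl <- cipControl(nu = 4, v1 = 0.05, v2 = 0.05, eta = 0,
                    family = "exponential", lambda = 0.3)
  kf <- fitKernelCip(ds, ctl, kernelSpec("rbf", sigma = tauSquared(features(ds)) / 4))
  accK <- mean(predict(kf, features(ds)) == classLabels(ds))
  expect_gte(accK, 0.95)
  # the linear fit cannot do this
  lf <- fitLinearCip(ds, ctl)
  accL <- mean(predict(lf, features(ds)) == classLabels(ds))
  expect_gt(accK, accL)
})
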