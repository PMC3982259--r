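test_that("eta = 0 gives the plain Gram quadratic form; eta > 0 matches a dense-inverse oracle", {
  ds <- randomDataset(101, nPos = 4, nNeg = 2, dim = 2)
  mu <- rep(1, 6)   # memberships play no role in the H assembly under test
  X <- features(ds)
  y <- classLabels(ds)
  dp0 <- assembleLinearDual(ds, mu, cipControl(nu = 0.5, v1 = 0.1, v2 = 0.1, eta = 0))
  expect_equal(dp0@H, tcrossprod(X) * tcrossprod(y), tolerance = 1e-12)
  g <- withinClassGraph(ds, k = 2, t = 1)
  S <- scatterLinear(ds, g)
  ctl <- cipControl(nu = 0.5, v1 = 0.1, v2 = 0.1, eta = 1, k = 2, t = 1)
  dp <- assembleLinearDual(ds, mu, ctl, S)
  Ainv <- solve(diag(2) + S)   # explicit-inverse oracle, entry by entry
  Href <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    Href[i, j] <- y[i] * y[j] * (X[i, ] %*% Ainv %*% X[j, ])
  expect_equal(dp@H, Href, tolerance = 1e-10)
  # regularization limit: H(eta) -> H(0) as eta -> 0
  for (eta in c(1e-3, 1e-6)) {
    ctlE <- cipControl(nu = 0.5, v1 = 0.1, v2 = 0.1, eta = eta, k = 2, t = 1)
    dH <- max(abs(assembleLinearDual(ds, mu, ctlE, S)@H - dp0@H))
    expect_lt(dH, eta * 10 * max(abs(dp0@H)) * max(abs(S)))
  }
})

test_that("infeasible nu is rejected naming the limiting class", {
  ds <- randomDataset(102, nPos = 5, nNeg = 3)
  mu <- rep(1, 8)
  # negative bound mass = sum(1/(v2*3)) = 1/v2; nu above it is infeasible
  ctl <- cipControl(nu = 11, v1 = 0.01, v2 = 0.1)
  expect_error(assembleLinearDual(ds, mu, ctl), "negative")
})

test_that("two-point dual is pinned to alpha = (nu, nu) and the geometry is analytic", {
  # +e1 labeled +1, -e1 labeled -1; mu = 1, eta = 0
  ds <- cipDataSet(rbind(c(1, 0), c(-1, 0)), c(1, -1))
  mu <- c(1, 1)
  ctl <- cipControl(nu = 0.3, v1 = 0.5, v2 = 0.5, eta = 0)
  dp <- assembleLinearDual(ds, mu, ctl)
  sol <- solveDual(dp)
  expect_equal(sol$alpha, c(0.3, 0.3), tolerance = 1e-8)
  fit <- recoverLinear(ds, mu, ctl, NULL, sol)
  # w = sum alpha y x = 0.6 * e1
  expect_equal(fit@w, c(0.6, 0), tolerance = 1e-8)
  # b* = 1 - w'x_1 = 0.4 ; rho from the negative margin:
  # -(w'x_2 + b) = 1 + rho  =>  rho = 0.6 - 0.4 - 1 = -0.8
  expect_equal(fit@bStar, 1 - 0.6, tolerance = 1e-8)
  expect_equal(fit@rhoStar, -0.8, tolerance = 1e-8)
  expect_equal(fit@kkt$bKKT, fit@bStar, tolerance = 1e-7)
  expect_equal(fit@kkt$rhoKKT, fit@rhoStar, tolerance = 1e-7)
  # halfspace prediction matches the analytic boundary x1 = -b/w1
  grid <- cbind(seq(-3, 3, by = 0.25), 0)
  expect_equal(predict(fit, grid), ifelse(0.6 * grid[, 1] + 0.4 >= 0, 1, -1))
  # decision ties map to +1
  tie <- matrix(c(-0.4 / 0.6, 0), 1)
  expect_equal(predict(fit, tie), 1)
})

test_that("H = 0 (all points at the origin) still yields a feasible solution", {
  ds <- cipDataSet(matrix(0, 4, 2), c(1, 1, -1, -1))
  dp <- new("CipDual", H = matrix(0, 4, 4), ub = rep(1, 4), nu = 1, m1 = 2L)
  sol <- solveDual(dp)
  expect_equal(sum(sol$alpha[1:2]), 1, tolerance = 1e-7)
  expect_equal(sum(sol$alpha[3:4]), 1, tolerance = 1e-7)
  expect_true(all(sol$alpha >= -1e-9 & sol$alpha <= 1 + 1e-9))
  expect_equal(sol$objective, 0, tolerance = 1e-10)
})

test_that("dual objective matches the independent FISTA oracle on small instances", {
  for (seed in 1:6) {
    ds <- randomDataset(seed + 200, nPos = 5, nNeg = 3, dim = 3)
    mu <- linearMembership(ds)
    ctl <- feasibleControl(ds, mu, frac = 0.5, eta = if (seed %% 2) 0.8 else 0,
                           k = 2, t = 1)
    S <- if (ctl$eta > 0) scatterLinear(ds, withinClassGraph(ds, 2, 1)) else NULL
    dp <- assembleLinearDual(ds, mu, ctl, S)
    sol <- solveDual(dp)
    orc <- oracleDualQP(dp@H, dp@ub, dp@nu, 5L)
    denom <- max(abs(orc$objective), 1e-10)
    expect_lt(abs(sol$objective - orc$objective) / denom, 1e-6)
  }
})

test_that("solved instances satisfy the KKT system", {
  for (seed in 4:9) {
    ds <- randomDataset(seed + 300, nPos = 6, nNeg = 4, dim = 2, sep = 1)
    mu <- exponentialMembership(ds, 0.5)
    ctl <- feasibleControl(ds, mu, frac = 0.35, eta = 0.5, k = 3, t = 2,
                           family = "exponential")
    S <- scatterLinear(ds, withinClassGraph(ds, 3, 2))
    dp <- assembleLinearDual(ds, mu, ctl, S)
    sol <- solveDual(dp)
    r <- sol$residuals
    expect_lt(r$eqPos, 1e-6 * ctl$nu)
    expect_lt(r$eqNeg, 1e-6 * ctl$nu)
    expect_lte(r$box, 1e-9)
    expect_lt(r$compLower, 1e-6)
    expect_lt(r$compUpper, 1e-6)
    # interior SVs sit on their class margin at the KKT thresholds
    fit <- recoverLinear(ds, mu, ctl, S, sol)
    f <- features(ds) %*% fit@w
    tolsv <- 1e-6 * max(dp@ub)
    intPos <- which(sol$alpha > tolsv & sol$alpha < dp@ub - tolsv &
                    seq_len(10) <= 6)
    if (length(intPos))
      expect_equal(unname(f[intPos] + sol$bKKT), rep(1, length(intPos)),
                   tolerance = 1e-5)
  }
})

test_that("margin-mass bounds hold on noisy synthetic fits and reduce sensibly", {
  for (seed in 1:4) {
    ds <- simulateDataset(simSpec(nPos = 25, nNeg = 8, dim = 3, separation = 1.5,
                                  labelNoiseRate = 0.1, seed = seed))
    ctl <- cipControl(nu = 4, v1 = 0.05, v2 = 0.05, eta = 0.5, k = 3, t = 2)
    fit <- fitLinearCip(ds, ctl)
    rep <- marginBoundsReport(fit)
    expect_true(all(rep$lowerHolds | rep$lowerVacuous))
    expect_true(all(rep$upperHolds))
    expect_true(all(is.finite(rep$middle)))
    expect_true(all(rep$meanMuSV > 0 & rep$meanMuSV <= 1, na.rm = TRUE))
  }
  # separable toy with error costs above the rho reward: no margin errors,
  # left bounds vacuous
  dsSep <- simulateDataset(simSpec(nPos = 15, nNeg = 6, dim = 2, separation = 8,
                                   seed = 9))
  ctlSep <- cipControl(nu = 0.5, v1 = 0.005, v2 = 0.005)
  fitSep <- fitLinearCip(dsSep, ctlSep)
  repSep <- marginBoundsReport(fitSep)
  # chains hold; the linear membership's farthest sample has mu ~ delta/dmax
  # and may be capped into a margin error even on separable data
  expect_true(all(repSep$lowerHolds | repSep$lowerVacuous))
  expect_true(all(repSep$upperHolds))
  # all mu = 1: no down-weighted stragglers, no margin errors at all, and
  # the masses reduce to plain counts
  fitOne <- fitLinearCip(dsSep, ctlSep, mu = rep(1, 21))
  repOne <- marginBoundsReport(fitOne)
  expect_true(all(repOne$lowerVacuous))
  expect_equal(repOne$svMass, repOne$nSV)
})

test_that("cheapening minority errors does not decrease training specificity", {
  ds <- simulateDataset(simSpec(nPos = 40, nNeg = 8, dim = 2, separation = 1.2,
                                seed = 77))
  specOf <- function(v2) {
    fit <- fitLinearCip(ds, cipControl(nu = 3, v1 = 0.05, v2 = v2))
    scoreClassifier(classLabels(ds), predict(fit, features(ds)))$specificity
  }
  s <- vapply(c(0.05, 0.01, 0.002), specOf, numeric(1))
  # specificity non-decreasing as minority errors get more expensive
  # (tolerance: one sample = 1/8)
  expect_true(all(diff(s) >= -1 / 8 - 1e-12))
})
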