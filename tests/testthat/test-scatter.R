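test_that("within-class kNN support matches a brute-force all-pairs sort", {
  set.seed(8)
  ds <- randomDataset(8, nPos = 8, nNeg = 5, dim = 2)
  X <- features(ds)
  y <- classLabels(ds)
  D2 <- as.matrix(dist(X))^2
  sup <- knnWithinClass(y, D2, 3)
  # brute force with the same smaller-index tie rule
  ref <- matrix(FALSE, 13, 13)
  for (i in 1:13) {
    others <- setdiff(which(y == y[i]), i)
    nn <- others[order(D2[i, others], others)][1:3]
    ref[i, nn] <- TRUE
  }
  expect_identical(sup, ref | t(ref))
  expect_true(isSymmetric(sup))
  expect_false(any(sup & outer(y, y, "!=")))   # never crosses classes
  expect_false(any(diag(sup)))
})

test_that("k is truncated to class size minus one, giving a clique", {
  ds <- cipDataSet(rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5)),
                   c(1, 1, 1, -1, -1))
  D2 <- as.matrix(dist(features(ds)))^2
  expect_warning(sup <- knnWithinClass(classLabels(ds), D2, 10), "truncated")
  for (cl in c(1, -1)) {
    idx <- which(classLabels(ds) == cl)
    expect_true(all(sup[idx, idx][upper.tri(diag(length(idx)))]))
  }
})

test_that("heat weights row-normalize and respect the middle-point example", {
  # 3 collinear positives, middle point equidistant from both ends
  ds <- cipDataSet(matrix(c(0, 1, 2, 9), 4, 1), c(1, 1, 1, -1))
  D2 <- as.matrix(dist(features(ds)))^2
  sup <- knnWithinClass(classLabels(ds), D2, 1)
  # middle point is neighbor of both ends (symmetric OR)
  expect_true(sup[1, 2] && sup[3, 2])
  g <- heatWeights(sup, D2, t = 1)
  expect_equal(g@W[2, 1], 0.5)  # equidistant neighbors split evenly
  expect_equal(g@W[2, 3], 0.5)
  rs <- rowSums(g@W)
  expect_equal(rs[1:3], rep(1, 3))
  expect_equal(rs[4], 0)        # isolated singleton row stays zero
  # hand evaluation of each supported entry at t = 1
  raw <- exp(-D2) * sup
  expect_equal(g@W, unname(raw / pmax(rowSums(raw), .Machine$double.xmin) *
                 (rowSums(raw) > 0)), tolerance = 1e-12)
  # very large t: all supported weights in a row become equal
  g2 <- heatWeights(sup, D2, t = 1e12)
  expect_equal(g2@W[2, c(1, 3)], c(0.5, 0.5), tolerance = 1e-9)
})

test_that("scatter matrix: outer-product accumulation equals the matrix form", {
  for (seed in c(2, 12, 22)) {
    ds <- randomDataset(seed, nPos = 6, nNeg = 4, dim = 2)
    g <- withinClassGraph(ds, k = 2, t = 1.5)
    S <- scatterLinear(ds, g)
    # direct outer-product accumulation per sample
    X <- features(ds)
    Sref <- matrix(0, 2, 2)
    for (i in 1:10) {
      if (sum(g@W[i, ]) == 0) next  # isolated: contributes nothing
      r <- X[i, ] - colSums(g@W[i, ] * X)
      Sref <- Sref + tcrossprod(r)
    }
    expect_equal(S, Sref, tolerance = 1e-10)
    expect_true(isSymmetric(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
})

test_that("degenerate classes give a zero scatter", {
  # single-point classes: no neighbors, no contribution
  ds1 <- cipDataSet(rbind(c(1, 2), c(3, 4)), c(1, -1))
  g1 <- suppressWarnings(withinClassGraph(ds1, k = 1, t = 1))
  expect_equal(scatterLinear(ds1, g1), matrix(0, 2, 2))
  # identical class members: residuals vanish
  ds2 <- cipDataSet(rbind(c(1, 1), c(1, 1), c(1, 1), c(4, 0), c(4, 0)),
                    c(1, 1, 1, -1, -1))
  g2 <- withinClassGraph(ds2, k = 2, t = 1)
  expect_equal(scatterLinear(ds2, g2), matrix(0, 2, 2), tolerance = 1e-14)
})

test_that("scatter is invariant to permuting samples within a class", {
  ds <- randomDataset(33, nPos = 7, nNeg = 4, dim = 3)
  S1 <- scatterLinear(ds, withinClassGraph(ds, k = 3, t = 2))
  X <- features(ds)
  set.seed(7)
  perm <- c(sample(1:7), sample(8:11))
  ds2 <- cipDataSet(X[perm, ], classLabels(ds)[perm])
  S2 <- scatterLinear(ds2, withinClassGraph(ds2, k = 3, t = 2))
  expect_equal(S1, S2, tolerance = 1e-10)
})

test_that("kernel scatter with the linear kernel conjugates the linear scatter", {
  ds <- randomDataset(44, nPos = 4, nNeg = 3, dim = 2)
  X <- features(ds)
  y <- classLabels(ds)
  K <- tcrossprod(X)
  gk <- kernelWithinClassGraph(K, y, k = 2, t = 1.5)
  gl <- withinClassGraph(ds, k = 2, t = 1.5)
  # kernel-induced distances equal Euclidean ones, so the graphs agree
  expect_equal(gk@W, gl@W, tolerance = 1e-10)
  Ts <- scatterKernel(K, y, gk)
  S <- scatterLinear(ds, gl)
  expect_equal(Ts$T1 + Ts$T2, X %*% S %*% t(X), tolerance = 1e-8)
})

test_that("kernel scatter terms are symmetric PSD and vanish for identical members", {
  ds <- randomDataset(55, nPos = 4, nNeg = 3, dim = 2)
  K <- gramMatrix(features(ds), spec = kernelSpec("rbf", sigma = 1.3))
  g <- kernelWithinClassGraph(K, classLabels(ds), k = 2, t = 1)
  Ts <- scatterKernel(K, classLabels(ds), g)
  for (Tm in Ts) {
    expect_true(isSymmetric(Tm))
    ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev), 1e-12))
  }
  X2 <- rbind(c(1, 1), c(1, 1), c(0, 5), c(0, 5), c(0, 5))
  y2 <- c(1, 1, -1, -1, -1)
  K2 <- gramMatrix(X2, spec = kernelSpec("rbf", sigma = 2))
  g2 <- kernelWithinClassGraph(K2, y2, k = 1, t = 1)
  Ts2 <- scatterKernel(K2, y2, g2)
  expect_equal(Ts2$T1, matrix(0, 5, 5), tolerance = 1e-12)
  expect_equal(Ts2$T2, matrix(0, 5, 5), tolerance = 1e-12)
})
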