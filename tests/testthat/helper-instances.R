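# Small random instances shared across tests.  All draws are seeded by the
# caller through withr-free local seeding (the helpers take a seed).

randomDataset <- function(seed, nPos = 6, nNeg = 4, dim = 3, sep = 1.5) {
  set.seed(seed)
  Xp <- matrix(rnorm(nPos * dim), nPos, dim)
  Xn <- matrix(rnorm(nNeg * dim), nNeg, dim)
  Xn[, 1] <- Xn[, 1] + sep
  cipDataSet(rbind(Xp, Xn), c(rep(1, nPos), rep(-1, nNeg)))
}

# Hyperparameters with comfortably feasible nu for a given instance.
feasibleControl <- function(ds, mu, frac = 0.4, v1 = 0.1, v2 = 0.1, ...) {
  N <- nrow(features(ds))
  m1 <- nPos(ds)
  massPos <- sum(mu[seq_len(m1)] / (v1 * m1))
  massNeg <- sum(mu[seq.int(m1 + 1, N)] / (v2 * (N - m1)))
  cipControl(nu = frac * min(massPos, massNeg), v1 = v1, v2 = v2, ...)
}
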