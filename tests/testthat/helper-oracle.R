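# Independent QP oracle: accelerated projected gradient (FISTA) on
#   min (1/2) a' H a  s.t.  sum(a[pos]) = nu, sum(a[neg]) = nu, 0 <= a <= ub
# with an exact capped-simplex projection per class (bisection on the shift).
# Shares no code path with the package's interior-point + active-set solver.

projCappedSimplex <- function(v, u, s) {
  # projection of v onto {0 <= x <= u, sum(x) = s}; x(theta) = clamp(v - theta)
  lo <- min(v - u) - 1
  hi <- max(v) + 1
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    tot <- sum(pmin(pmax(v - mid, 0), u))
    if (tot > s) lo <- mid else hi <- mid
  }
  pmin(pmax(v - (lo + hi) / 2, 0), u)
}

oracleDualQP <- function(H, ub, nu, m1, iters = 30000) {
  N <- length(ub)
  pos <- seq_len(m1)
  neg <- seq.int(m1 + 1L, N)
  proj <- function(a) {
    a[pos] <- projCappedSimplex(a[pos], ub[pos], nu)
    a[neg] <- projCappedSimplex(a[neg], ub[neg], nu)
    a
  }
  a <- proj(rep(0, N))
  L <- max(abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values), 1e-12)
  z <- a
  tprev <- 1
  obj <- function(a) 0.5 * sum(a * (H %*% a))
  best <- obj(a)
  for (it in seq_len(iters)) {
    anew <- proj(z - (H %*% z) / L)
    tnew <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    z <- anew + ((tprev - 1) / tnew) * (anew - a)
    a <- anew
    tprev <- tnew
    if (it %% 500 == 0) {
      o <- obj(a)
      if (abs(best - o) < 1e-14 * max(1, abs(o))) { best <- o; break }
      best <- o
    }
  }
  list(alpha = a, objective = obj(a))
}
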