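# Dual QP machinery shared by the linear and kernel fits:
#   minimize (1/2) a' H a
#   s.t.     sum(a[pos]) = nu, sum(a[neg]) = nu, 0 <= a <= ub.
# kernlab::ipop provides the interior-point solve; an active-set polish then
# tightens the KKT residuals and yields the equality multipliers (lambda1,
# lambda2), from which the KKT-consistent thresholds are
#   b_kkt = 1 + lambda1,  rho_kkt = -(lambda1 + lambda2) - 2.

#' KKT residuals of a candidate dual solution
#'
#' Given alpha and the equality multipliers, reports the equality-constraint
#' gaps, box violations, and the complementarity residuals
#' max_i alpha_i * gamma_i and max_i (ub_i - alpha_i) * zeta_i, where
#' gamma/zeta are the minimal-norm bound multipliers implied by stationarity.
#' If \code{lambda} is missing it is estimated from the interior support
#' vectors of each class.
#'
#' @param H,ub,nu,m1 the dual problem data (see \linkS4class{CipDual})
#' @param alpha candidate solution
#' @param lambda optional numeric(2) equality multipliers
#' @return list with fields \code{eqPos}, \code{eqNeg}, \code{box},
#'   \code{compLower}, \code{compUpper}, \code{max} (worst residual),
#'   \code{lambda}
#' @export
kktResiduals <- function(H, ub, nu, m1, alpha, lambda = NULL) {
  N <- length(alpha)
  pos <- .posIdx(m1)
  neg <- .negIdx(m1, N)
  g <- as.numeric(H %*% alpha)
  tolAct <- 1e-7 * max(ub)
  if (is.null(lambda)) {
    est <- function(idx) {
      int <- idx[alpha[idx] > tolAct & alpha[idx] < ub[idx] - tolAct]
      if (length(int)) -mean(g[int]) else -stats::median(g[idx])
    }
    lambda <- c(est(pos), est(neg))
  }
  s <- g + ifelse(seq_len(N) %in% pos, lambda[1], lambda[2])
  gam <- pmax(s, 0)
  zet <- pmax(-s, 0)
  res <- list(
    eqPos = abs(sum(alpha[pos]) - nu),
    eqNeg = abs(sum(alpha[neg]) - nu),
    box = max(0, max(-alpha), max(alpha - ub)),
    compLower = max(alpha * gam),
    compUpper = max((ub - alpha) * zet),
    lambda = lambda
  )
  res$max <- max(res$eqPos, res$eqNeg, res$box, res$compLower, res$compUpper)
  res
}

# One active-set refinement pass: fix variables judged at a bound, solve the
# equality-constrained KKT system on the free set, and move the worst
# violator between sets.  Warm-started at the interior-point solution this
# typically terminates in a handful of iterations with residuals at linear
# solve precision.
.polishActiveSet <- function(H, ub, nu, m1, alpha0, maxPasses = 200L) {
  N <- length(alpha0)
  pos <- .posIdx(m1)
  neg <- .negIdx(m1, N)
  clsOf <- ifelse(seq_len(N) <= m1, 1L, 2L)
  thr <- 1e-7 * max(ub)
  alpha <- pmin(pmax(alpha0, 0), ub)
  lower <- alpha <= thr
  upper <- ub - alpha <= thr
  lambda <- c(NA_real_, NA_real_)
  bestState <- NULL
  bestRes <- Inf

  for (pass in seq_len(maxPasses)) {
    free <- which(!lower & !upper)
    fixedU <- which(upper)
    aFix <- numeric(N)
    aFix[fixedU] <- ub[fixedU]
    # equality rows, one per class that still has free variables
    Ecls <- unique(clsOf[free])
    nf <- length(free)
    nE <- length(Ecls)
    rhsEq <- vapply(Ecls, function(cc) {
      nu - sum(aFix[intersect(if (cc == 1L) pos else neg, fixedU)])
    }, numeric(1))
    if (nf > 0) {
      # null-space method: the equality rows are disjoint class indicators,
      # so a particular solution spreads each class target equally and the
      # reduced problem over the null-space coordinates is an unconstrained
      # PSD quadratic whose normal system is always consistent -- safe to
      # pseudo-invert even when H is rank-deficient, and the equalities
      # hold exactly by construction
      Hff <- H[free, free, drop = FALSE]
      cF <- as.numeric(H[free, fixedU, drop = FALSE] %*% ub[fixedU])
      E <- matrix(0, nE, nf)
      for (r in seq_len(nE)) E[r, clsOf[free] == Ecls[r]] <- 1
      aP <- numeric(nf)
      for (r in seq_len(nE)) {
        inC <- clsOf[free] == Ecls[r]
        aP[inC] <- rhsEq[r] / sum(inC)
      }
      aF <- aP
      if (nf > nE) {
        Z <- qr.Q(qr(t(E)), complete = TRUE)[, (nE + 1):nf, drop = FALSE]
        Hn <- crossprod(Z, Hff %*% Z)
        rn <- -as.numeric(crossprod(Z, Hff %*% aP + cF))
        z <- tryCatch(solve(.symmetrize(Hn), rn), error = function(e) NULL)
        if (is.null(z) || !all(is.finite(z))) {
          sv <- svd(.symmetrize(Hn))
          keep <- sv$d > max(sv$d, 0) * 1e-12
          z <- if (any(keep))
            as.numeric(sv$v[, keep, drop = FALSE] %*%
                         ((t(sv$u[, keep, drop = FALSE]) %*% rn) / sv$d[keep]))
          else numeric(ncol(Z))
        }
        aF <- aP + as.numeric(Z %*% z)
      }
      alpha <- aFix
      alpha[free] <- aF
      # per-class multipliers from the stationarity residuals of free vars
      statF <- as.numeric(Hff %*% aF) + cF
      for (r in seq_len(nE))
        lambda[Ecls[r]] <- -mean(statF[clsOf[free] == Ecls[r]])
    } else {
      alpha <- aFix
    }
    # for classes with no free variables, pick lambda inside the dual
    # feasibility interval implied by the bound variables
    g <- as.numeric(H %*% alpha)
    for (cc in 1:2) {
      if (cc %in% Ecls) next
      idx <- if (cc == 1L) pos else neg
      lo <- suppressWarnings(max(-g[idx][upper[idx]], -Inf))
      hi <- suppressWarnings(min(-g[idx][lower[idx]], Inf))
      lambda[cc] <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
        else if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
    }
    # primal violations among free vars
    viol <- numeric(N)
    viol[free] <- pmax(-alpha[free], alpha[free] - ub[free])
    # dual violations among bound vars
    s <- g + ifelse(clsOf == 1L, lambda[1], lambda[2])
    dv <- numeric(N)
    dv[lower] <- pmax(-s[lower], 0)
    dv[upper] <- pmax(s[upper], 0)
    # a class whose variables are all fixed can miss its equality target;
    # that is a violation too and needs a variable freed
    eqViol <- 0
    eqClass <- 0L
    for (cc in 1:2) {
      if (cc %in% Ecls) next
      idx <- if (cc == 1L) pos else neg
      v <- abs(sum(alpha[idx]) - nu)
      if (v > eqViol) { eqViol <- v; eqClass <- cc }
    }
    worstP <- which.max(viol)
    worstD <- which.max(dv)
    tolV <- 1e-9 * max(1, max(ub))
    # remember the best equality-feasible iterate seen (the active-set walk
    # can cycle on degenerate vertices)
    passRes <- max(viol[worstP], dv[worstD], eqViol)
    if (viol[worstP] <= tolV && eqViol <= tolV && passRes < bestRes) {
      bestRes <- passRes
      bestState <- list(alpha = pmin(pmax(alpha, 0), ub), lambda = lambda)
    }
    if (passRes <= tolV) break
    if (eqViol >= max(viol[worstP], dv[worstD])) {
      idx <- if (eqClass == 1L) pos else neg
      short <- sum(alpha[idx]) < nu
      # free the bound variables that can move in the needed direction
      tofree <- if (short) idx[lower[idx]] else idx[upper[idx]]
      if (length(tofree) == 0L) tofree <- idx[lower[idx] | upper[idx]]
      lower[tofree] <- FALSE
      upper[tofree] <- FALSE
    } else if (viol[worstP] >= dv[worstD]) {
      # clamp the worst free violator to its nearer bound
      if (alpha[worstP] > ub[worstP] / 2) upper[worstP] <- TRUE else lower[worstP] <- TRUE
    } else {
      lower[worstD] <- FALSE
      upper[worstD] <- FALSE
    }
  }
  alpha <- pmin(pmax(alpha, 0), ub)
  final <- list(alpha = alpha, lambda = lambda)
  if (is.null(bestState)) return(final)
  # prefer the recorded best iterate unless the final state beats it
  rFin <- kktResiduals(H, ub, nu, m1, final$alpha, final$lambda)
  rBest <- kktResiduals(H, ub, nu, m1, bestState$alpha, bestState$lambda)
  if (rFin$max <= rBest$max) final else bestState
}

#' Solve the fuzzy imbalance-aware dual QP
#'
#' Interior-point solve (kernlab's \code{ipop}) followed by an active-set
#' polish; the better of the two candidates under the KKT residual is
#' returned together with the equality multipliers and the implied
#' KKT-consistent thresholds.
#'
#' @param dp a \linkS4class{CipDual}
#' @param tol accepted KKT residual; a warning is raised if the final
#'   residual exceeds it
#' @return list with \code{alpha}, \code{lambda}, \code{residuals} (see
#'   [kktResiduals()]), \code{bKKT}, \code{rhoKKT}, \code{objective},
#'   \code{status}
#' @export
solveDual <- function(dp, tol = 1e-8) {
  H <- dp@H
  ub <- dp@ub
  nu <- dp@nu
  m1 <- dp@m1
  N <- length(ub)
  massPos <- sum(ub[.posIdx(m1)])
  massNeg <- sum(ub[.negIdx(m1, N)])
  if (massPos < nu || massNeg < nu) {
    lim <- if (massPos < massNeg) "positive" else "negative"
    stop(sprintf(paste0(
      "infeasible nu = %g: the %s class can carry at most %g ",
      "(sum of its upper bounds mu/(v*m)); lower nu or the class's v"),
      nu, lim, min(massPos, massNeg)))
  }
  A <- rbind(as.numeric(seq_len(N) <= m1), as.numeric(seq_len(N) > m1))
  ip <- tryCatch(
    kernlab::ipop(c = rep(0, N), H = H, A = A, b = c(nu, nu),
                  l = rep(0, N), u = ub, r = c(0, 0),
                  sigf = 8, maxiter = 200),
    error = function(e) NULL
  )
  status <- if (is.null(ip)) "ipop-error" else kernlab::how(ip)
  # scaled-bounds feasible point: also the start of choice near the vertex
  # where one class's equality pins it to its box bound
  aScaled <- ub
  aScaled[.posIdx(m1)] <- ub[.posIdx(m1)] * nu / massPos
  aScaled[.negIdx(m1, N)] <- ub[.negIdx(m1, N)] * nu / massNeg
  alphaRaw <- if (is.null(ip)) aScaled
    else pmin(pmax(kernlab::primal(ip), 0), ub)
  resRaw <- kktResiduals(H, ub, nu, m1, alphaRaw)
  best <- list(alpha = alphaRaw, lambda = resRaw$lambda, residuals = resRaw)
  starts <- if (max(abs(alphaRaw - aScaled)) > 0) list(alphaRaw, aScaled)
    else list(alphaRaw)
  for (a0 in starts) {
    pol <- .polishActiveSet(H, ub, nu, m1, a0)
    if (is.null(pol)) next
    resPol <- kktResiduals(H, ub, nu, m1, pol$alpha, pol$lambda)
    if (resPol$max < best$residuals$max)
      best <- list(alpha = pol$alpha, lambda = pol$lambda, residuals = resPol)
  }
  if (best$residuals$max > max(tol, 1e-6 * max(1, nu)))
    warning(sprintf("dual solve KKT residual %.3e exceeds tolerance %.1e",
                    best$residuals$max, tol))
  best$bKKT <- 1 + best$lambda[1]
  best$rhoKKT <- -(best$lambda[1] + best$lambda[2]) - 2
  best$objective <- 0.5 * sum(best$alpha * (H %*% best$alpha))
  best$status <- status
  best
}
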