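#' Hyperparameter bundle
#'
#' Collects the tunable parameters of the fuzzy imbalance-aware SVM.
#' \code{nu} is the margin-mass parameter (each class's dual multipliers sum
#' to \code{nu}); \code{v1}, \code{v2} scale the misclassification cost of
#' the positive (majority) and negative (minority) class -- the per-sample
#' cost is mu_i / (v_c m_c), so a SMALLER v makes that class's errors more
#' expensive; \code{eta} trades the local within-class scatter penalty
#' against the margin; \code{k}, \code{t} parameterize the within-class
#' neighbor graph; \code{family}, \code{delta}, \code{lambda} select the
#' fuzzy membership.
#'
#' @param nu margin-mass parameter (> 0)
#' @param v1,v2 class cost scalers (> 0)
#' @param eta scatter-margin tradeoff (>= 0)
#' @param k neighbor count for the locality graph
#' @param t heat-kernel width for the locality graph
#' @param family membership family, \code{"linear"} or \code{"exponential"}
#' @param delta linear-membership floor constant
#' @param lambda exponential-membership steepness in [0, 1]
#' @return validated list of class \code{"CipControl"}
#' @export
cipControl <- function(nu = 1, v1 = 0.01, v2 = 0.01, eta = 0,
                       k = 5, t = 1,
                       family = c("linear", "exponential"),
                       delta = 1e-6, lambda = 0.5) {
  family <- match.arg(family)
  .assertScalar(nu, "nu", lower = 0, strictLower = TRUE)
  .assertScalar(v1, "v1", lower = 0, strictLower = TRUE)
  .assertScalar(v2, "v2", lower = 0, strictLower = TRUE)
  .assertScalar(eta, "eta", lower = 0)
  .assertScalar(k, "k", lower = 1)
  .assertScalar(t, "t", lower = 0, strictLower = TRUE)
  .assertScalar(delta, "delta", lower = 0, strictLower = TRUE)
  .assertScalar(lambda, "lambda", lower = 0, upper = 1)
  structure(list(nu = nu, v1 = v1, v2 = v2, eta = eta, k = k, t = t,
                 family = family, delta = delta, lambda = lambda),
            class = "CipControl")
}

.dualUpperBounds <- function(mu, m1, N, v1, v2) {
  ub <- numeric(N)
  ub[.posIdx(m1)] <- mu[.posIdx(m1)] / (v1 * m1)
  ub[.negIdx(m1, N)] <- mu[.negIdx(m1, N)] / (v2 * (N - m1))
  ub
}

# Solve (I + eta S) Z = B without forming the inverse (S is PSD so the
# regularized operator is symmetric positive definite).
.regularizedSolve <- function(S, eta, B) {
  if (eta == 0) return(B)
  A <- diag(nrow(S)) + eta * S
  R <- chol(.symmetrize(A))
  backsolve(R, backsolve(R, B, transpose = TRUE))
}

#' Assemble the linear dual problem
#'
#' Builds H with entries y_i y_j x_i' (I + eta S)^{-1} x_j through one
#' symmetric factorization (never an explicit inverse), the fuzzy box upper
#' bounds mu_i/(v_c m_c), and the two equality targets nu.  Errors out if nu
#' exceeds the bound mass of either class (infeasible equality constraint).
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param mu fuzzy memberships (length N, in (0, 1])
#' @param control a [cipControl()] bundle
#' @param S local within-class scatter matrix from [scatterLinear()];
#'   ignored when \code{control$eta == 0}
#' @return a \linkS4class{CipDual}
#' @export
assembleLinearDual <- function(ds, mu, control, S = NULL) {
  N <- nrow(ds@X)
  if (length(mu) != N) stop("mu must have one membership per sample")
  if (control$eta > 0 && is.null(S))
    stop("a scatter matrix is required when eta > 0")
  G <- if (control$eta == 0) tcrossprod(ds@X)
    else ds@X %*% .regularizedSolve(S, control$eta, t(ds@X))
  H <- .symmetrize(G * tcrossprod(ds@y))
  ub <- .dualUpperBounds(mu, ds@m1, N, control$v1, control$v2)
  dp <- new("CipDual", H = H, ub = ub, nu = control$nu, m1 = ds@m1)
  massPos <- sum(ub[.posIdx(ds@m1)])
  massNeg <- sum(ub[.negIdx(ds@m1, N)])
  if (massPos < control$nu || massNeg < control$nu) {
    lim <- if (massPos < massNeg) "positive" else "negative"
    stop(sprintf("infeasible nu = %g: limiting class is the %s class (bound mass %g)",
                 control$nu, lim, min(massPos, massNeg)))
  }
  dp
}

# Support-vector threshold: scale-aware cut on solver noise.
.svTol <- function(ub) 1e-8 * max(ub)

# Margin errors are the samples with positive slack in the KKT sense: slacks
# are evaluated at the dual's equality-constraint multipliers (bKKT, rhoKKT)
# when available, since the SV-averaged thresholds reported for prediction
# shift once bound support vectors enter the average and would mislabel
# interior points.  The 1e-6 floor absorbs solver noise on the O(1) slack
# scale.
.marginErrorSets <- function(f, m1, bStar, rhoStar, kkt, tol = 1e-6) {
  b <- if (!is.null(kkt$bKKT)) kkt$bKKT else bStar
  r <- if (!is.null(kkt$rhoKKT)) kkt$rhoKKT else rhoStar
  N <- length(f)
  pos <- .posIdx(m1)
  neg <- .negIdx(m1, N)
  xiPos <- pmax(0, 1 - (f[pos] + b))
  xiNeg <- pmax(0, 1 + r + (f[neg] + b))
  list(me1 = as.integer(pos[xiPos > tol]), me2 = as.integer(neg[xiNeg > tol]))
}

#' Recover the linear model from a dual solution
#'
#' Computes the weight vector w* = (I + eta S)^{-1} sum_i alpha_i y_i x_i,
#' the support-vector sets per class, the thresholds by solving the active
#' margin equations per support vector and averaging over each class
#' (b* = 1 - mean of w*'x over positive SVs; rho* = mean over positive SVs
#' - mean over negative SVs - 2, the averaged per-SV solution of
#' -(w*'x_j + b*) = 1 + rho), the reconstructed slacks, and the
#' margin-error sets.
#'
#' The reported support-vector sets follow the closed-interval definition
#' (all alpha > tol).  The threshold averages, however, run over the SVs the
#' margin equalities actually hold for -- those with zero slack, i.e. the
#' interior SVs (0 < alpha < bound) -- since bound SVs may sit off their
#' margin and would bias the averages; \code{svRule = "all"} restores the
#' bound-inclusive averaging.  When a class has no interior SV the
#' thresholds come from a direct convex line search on the primal cost.
#'
#' @inheritParams assembleLinearDual
#' @param alpha dual solution vector, or the full list from [solveDual()]
#' @param svRule SV set used for the threshold averages:
#'   \code{"interior"} (default) or \code{"all"}
#' @return a \linkS4class{LinearCipModel}
#' @export
recoverLinear <- function(ds, mu, control, S = NULL, alpha,
                          svRule = c("interior", "all")) {
  svRule <- match.arg(svRule)
  kkt <- list()
  if (is.list(alpha)) {
    kkt <- alpha[intersect(names(alpha),
                           c("lambda", "residuals", "bKKT", "rhoKKT",
                             "status", "effectiveNu"))]
    alpha <- alpha$alpha
  }
  if (control$eta > 0 && is.null(S))
    stop("a scatter matrix is required when eta > 0")
  N <- nrow(ds@X)
  ub <- .dualUpperBounds(mu, ds@m1, N, control$v1, control$v2)
  tol <- .svTol(ub)
  w <- as.numeric(.regularizedSolve(S, control$eta,
                                    crossprod(ds@X, alpha * ds@y)))
  pos <- .posIdx(ds@m1)
  neg <- .negIdx(ds@m1, N)
  isSV <- alpha > tol
  sv1 <- pos[isSV[pos]]
  sv2 <- neg[isSV[neg]]
  if (length(sv1) == 0L || length(sv2) == 0L)
    stop("no support vectors in the ", if (length(sv1)) "negative" else "positive",
         " class; increase nu or revisit v1/v2")
  f <- as.numeric(ds@X %*% w)
  interior <- isSV & (alpha < ub - tol)
  th1 <- if (svRule == "interior") pos[interior[pos]] else sv1
  th2 <- if (svRule == "interior") neg[interior[neg]] else sv2
  if (length(th1) && length(th2)) {
    bStar <- 1 - mean(f[th1])
    rhoStar <- mean(f[th1]) - mean(f[th2]) - 2
    kkt$recovery <- "margin-average"
  } else {
    pt <- .primalThresholds(f, ds@m1, mu, control, control$nu)
    bStar <- pt$b
    rhoStar <- pt$rho
    kkt$recovery <- "primal-linesearch"
    kkt$bKKT <- NULL
    kkt$rhoKKT <- NULL
  }
  xi <- numeric(N)
  xi[pos] <- pmax(0, 1 - (f[pos] + bStar))
  xi[neg] <- pmax(0, 1 + rhoStar + (f[neg] + bStar))
  me <- .marginErrorSets(f, ds@m1, bStar, rhoStar, kkt)
  new("LinearCipModel",
    alpha = alpha, w = w, bStar = bStar, rhoStar = rhoStar,
    sv1 = as.integer(sv1), sv2 = as.integer(sv2),
    me1 = me$me1, me2 = me$me2,
    xi = xi, mu = mu, control = unclass(control), kkt = kkt,
    m1 = ds@m1
  )
}

# Enforce the primal's rho >= 0 constraint at the fit level.  With rho
# unconstrained the dual pins both class sums at nu (the printed equality
# form); with rho >= 0 (multiplier s >= 0) the true dual lets the common sum
# grow: it minimizes W(nu') = V(nu') - 2 nu' over nu' in [nu, bound mass],
# where V is the equality-QP optimal value (the -2 nu' term is the dual's
# linear part, constant at fixed sums).  W is convex, so a derivative-free
# golden-section search on the QP objective is robust even where the
# equality multipliers are degenerate.  Whenever the unconstrained rho is
# already nonnegative, the solution at nu is returned untouched.
.solveEnforcingRho <- function(dp, relTol = 5e-3) {
  at <- function(nu2) {
    dp2 <- new("CipDual", H = dp@H, ub = dp@ub, nu = nu2, m1 = dp@m1)
    # intermediate bracketing solves may sit at degenerate vertices; only
    # the returned solution's quality is reported
    s <- suppressWarnings(solveDual(dp2))
    s$effectiveNu <- nu2
    s
  }
  sol <- at(dp@nu)
  if (sol$rhoKKT >= -1e-6) return(sol)
  N <- length(dp@ub)
  # the upper end of the feasible common-sum range: one class entirely at
  # its box bound (the equality is attainable at the vertex)
  nuMax <- min(sum(dp@ub[.posIdx(dp@m1)]), sum(dp@ub[.negIdx(dp@m1, N)]))
  if (nuMax <= dp@nu) return(sol)
  W <- function(s) s$objective - 2 * s$effectiveNu
  gr <- (sqrt(5) - 1) / 2
  a <- dp@nu
  b <- nuMax
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  s1 <- at(x1); s2 <- at(x2)
  cand <- list(sol, at(nuMax), s1, s2)
  while (b - a > relTol * (nuMax - dp@nu)) {
    if (W(s1) <= W(s2)) {
      b <- x2; x2 <- x1; s2 <- s1
      x1 <- b - gr * (b - a); s1 <- at(x1)
    } else {
      a <- x1; x1 <- x2; s1 <- s2
      x2 <- a + gr * (b - a); s2 <- at(x2)
    }
    cand <- c(cand, list(s1, s2))
  }
  best <- cand[[which.min(vapply(cand, W, numeric(1)))]]
  if (best$residuals$max > 1e-6 * max(1, best$effectiveNu))
    warning(sprintf("KKT residual %.3e at the selected effective class sum %.4g",
                    best$residuals$max, best$effectiveNu))
  best
}

# Primal-side threshold recovery: minimize, for the fitted w, the convex
# piecewise-linear primal cost in (b, rho) with rho >= 0:
#   -nu*rho + sum_i c_i max(0, 1 - f_i - b) + sum_j c_j max(0, 1 + rho + f_j + b)
# Used when a class has no interior support vector, where the margin-average
# formulas (which presuppose active margin equalities) are undetermined.
.primalThresholds <- function(f, m1, mu, control, nu) {
  N <- length(f)
  pos <- .posIdx(m1)
  neg <- .negIdx(m1, N)
  c1 <- mu[pos] / (control$v1 * m1)
  c2 <- mu[neg] / (control$v2 * (N - m1))
  span <- max(abs(f)) + 3
  costRho <- function(b) {
    h <- function(rho) -nu * rho +
      sum(c1 * pmax(0, 1 - f[pos] - b)) +
      sum(c2 * pmax(0, 1 + rho + f[neg] + b))
    op <- stats::optimize(h, c(0, 2 * span + 2), tol = 1e-9 * span)
    # rho = 0 is admissible and often the exact corner solution
    if (h(0) <= op$objective) list(rho = 0, value = h(0))
    else list(rho = op$minimum, value = op$objective)
  }
  ob <- stats::optimize(function(b) costRho(b)$value, c(-span, span),
                        tol = 1e-9 * span)
  list(b = ob$minimum, rho = costRho(ob$minimum)$rho)
}

#' Fit the linear fuzzy imbalance-aware SVM
#'
#' End-to-end fit: fuzzy memberships, within-class locality graph and
#' scatter (when eta > 0), dual assembly, QP solve, and recovery of
#' (w*, b*, rho*).
#'
#' The secondary margin offset is constrained nonnegative, as in the primal:
#' when the rho-free dual would return rho < 0 (heavily overlapping
#' classes), the fit re-solves at the larger effective class-sum at which
#' rho = 0; the effective value is recorded in the model's \code{kkt} slot
#' as \code{effectiveNu}.  Set \code{enforceRhoNonneg = FALSE} for the
#' rho-free behavior.
#'
#' @param ds a \linkS4class{CipDataSet} (training data)
#' @param control a [cipControl()] bundle
#' @param mu optional membership vector; computed from
#'   \code{control$family} when missing
#' @param svRule see [recoverLinear()]
#' @param enforceRhoNonneg keep the minority margin offset nonnegative
#' @return a \linkS4class{LinearCipModel}
#' @examples
#' ds <- simulateDataset(simSpec(nPos = 40, nNeg = 8, dim = 2, seed = 1))
#' fit <- fitLinearCip(ds, cipControl(nu = 2, eta = 0.5))
#' table(truth = classLabels(ds), pred = predict(fit, features(ds)))
#' @export
fitLinearCip <- function(ds, control = cipControl(), mu = NULL,
                         svRule = c("interior", "all"),
                         enforceRhoNonneg = TRUE) {
  svRule <- match.arg(svRule)
  if (is.null(mu))
    mu <- fuzzyMembership(ds, control$family, control$delta, control$lambda)
  S <- NULL
  if (control$eta > 0)
    S <- scatterLinear(ds, withinClassGraph(ds, control$k, control$t))
  dp <- assembleLinearDual(ds, mu, control, S)
  sol <- if (enforceRhoNonneg) .solveEnforcingRho(dp) else solveDual(dp)
  recoverLinear(ds, mu, control, S, sol, svRule = svRule)
}

#' @describeIn decisionValues linear model: w*'x + b*
#' @export
setMethod("decisionValues", "LinearCipModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@w))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object@w))
  as.numeric(newdata %*% object@w) + object@bStar
})

.signPlus <- function(d) ifelse(d >= 0, 1, -1)

#' Predict labels
#'
#' sign(decision value), with sign(0) mapped to +1.
#'
#' @param object a fitted model
#' @param newdata numeric matrix of samples to classify
#' @param type \code{"class"} for labels, \code{"decision"} for scores
#' @return numeric labels in \{+1, -1\} or decision values
#' @export
setMethod("predict", "LinearCipModel",
  function(object, newdata, type = c("class", "decision")) {
    type <- match.arg(type)
    d <- decisionValues(object, newdata)
    if (type == "decision") d else .signPlus(d)
  }
)

#' Margin-mass bounds report
#'
#' Evaluates, per class, the inequality chain linking the membership mass of
#' the margin errors, the product nu * v_c * m_c, and the membership mass of
#' the support vectors:  sum of mu over MEs <= nu v_c m_c <= sum of mu over
#' SVs.  (Margin errors sit at their box bound, so their bound mass cannot
#' exceed the class's equality target; the SV bound mass must cover it.)
#' All six raw quantities are reported so the bound can be audited; the left
#' bound is vacuous (and flagged) when a class has no margin errors.
#' Margin errors are identified at the KKT-consistent thresholds (see
#' [recoverLinear()]), which is the notion of slack the bound is a statement
#' about.
#'
#' @param model a fitted \linkS4class{LinearCipModel} or
#'   \linkS4class{KernelCipModel}
#' @param tol relative slack for the numerical comparison
#' @return data.frame with one row per class: ME membership mass, the middle
#'   term, SV membership mass, counts, mean memberships, and pass flags
#' @export
marginBoundsReport <- function(model, tol = 1e-6) {
  ctl <- model@control
  m1 <- model@m1
  N <- length(model@alpha)
  m2 <- N - m1
  # the bound links the realized class sums of alpha; under the rho >= 0
  # enforcement those equal the effective nu
  nuEff <- if (!is.null(model@kkt$effectiveNu)) model@kkt$effectiveNu
    else ctl$nu
  rows <- lapply(list(
    list(cls = "positive", me = model@me1, sv = model@sv1, v = ctl$v1, m = m1),
    list(cls = "negative", me = model@me2, sv = model@sv2, v = ctl$v2, m = m2)
  ), function(z) {
    meMass <- sum(model@mu[z$me])
    svMass <- sum(model@mu[z$sv])
    middle <- nuEff * z$v * z$m
    eps <- tol * max(1, middle)
    data.frame(
      class = z$cls, nME = length(z$me), nSV = length(z$sv),
      meanMuME = if (length(z$me)) mean(model@mu[z$me]) else NA_real_,
      meanMuSV = if (length(z$sv)) mean(model@mu[z$sv]) else NA_real_,
      meMass = meMass, middle = middle, svMass = svMass,
      lowerHolds = meMass <= middle + eps,
      lowerVacuous = length(z$me) == 0L,
      upperHolds = middle <= svMass + eps,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
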