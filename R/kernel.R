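#' Kernel specification
#'
#' @param name \code{"rbf"} (Gaussian, K(u, v) = exp(-||u - v||^2 / sigma))
#'   or \code{"linear"} (K(u, v) = u'v).  Note the Gaussian spread sigma
#'   divides the squared distance directly (no factor 2).
#' @param sigma positive spread of the Gaussian kernel
#' @return validated list of class \code{"CipKernel"}
#' @seealso [tauSquared()], [sigmaGrid()] for the spread heuristic
#' @export
kernelSpec <- function(name = c("rbf", "linear"), sigma = NULL) {
  name <- match.arg(name)
  if (name == "rbf") {
    if (is.null(sigma)) stop("the rbf kernel requires 'sigma'")
    .assertScalar(sigma, "sigma", lower = 0, strictLower = TRUE)
  }
  structure(list(name = name, sigma = sigma), class = "CipKernel")
}

#' Gram matrix
#'
#' Kernel evaluations between the rows of \code{X} and \code{Xother}
#' (defaulting to \code{X} itself, giving the symmetric training Gram
#' matrix).
#'
#' @param X,Xother numeric matrices with matching feature count
#' @param spec a [kernelSpec()]
#' @return numeric \code{nrow(X)} x \code{nrow(Xother)} matrix
#' @export
gramMatrix <- function(X, Xother = NULL, spec) {
  X <- as.matrix(X)
  sym <- is.null(Xother)
  Y <- if (sym) X else as.matrix(Xother)
  if (ncol(X) != ncol(Y)) stop("feature dimensions disagree")
  if (spec$name == "linear") return(tcrossprod(X, Y))
  D2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  D2[D2 < 0] <- 0
  K <- exp(-D2 / spec$sigma)
  if (sym) .symmetrize(K) else K
}

#' Mean squared row norm
#'
#' The tau^2 statistic of the Gaussian-spread heuristic: the mean over
#' training samples of ||x||^2.  (The spread divides a squared distance, so
#' the squared norm is the dimensionally consistent reading of the "mean
#' norm" heuristic; \code{squared = FALSE} gives the literal mean of
#' \code{||x||}.)
#'
#' @param X training feature matrix
#' @param squared use squared norms (default)
#' @return positive scalar
#' @export
tauSquared <- function(X, squared = TRUE) {
  n2 <- rowSums(as.matrix(X)^2)
  if (squared) mean(n2) else mean(sqrt(n2))
}

#' Gaussian spread search grid
#'
#' tau^2 times powers of two from 1/16 to 16.
#'
#' @inheritParams tauSquared
#' @return numeric vector of nine candidate spreads
#' @export
sigmaGrid <- function(X, squared = TRUE) tauSquared(X, squared) * 2^(-4:4)

#' Regularized kernel operator
#'
#' Q = K + eta (T1 + T2), the Gram matrix plus the eta-weighted kernel-side
#' local within-class scatter terms.  Symmetric and PSD (sum of a Gram
#' matrix and PSD terms).
#'
#' @param K Gram matrix
#' @param y labels in \{+1, -1\}
#' @param graph kernel-space \linkS4class{WithinClassGraph}; may be NULL
#'   when \code{eta == 0}
#' @param eta scatter-margin tradeoff (>= 0)
#' @return symmetric N x N matrix
#' @export
assembleQ <- function(K, y, graph = NULL, eta = 0) {
  if (eta == 0) return(.symmetrize(K))
  if (is.null(graph)) stop("a kernel-space graph is required when eta > 0")
  Ts <- scatterKernel(K, y, graph)
  .symmetrize(K + eta * (Ts$T1 + Ts$T2))
}

# Cholesky of Q with a deterministic ridge escalation when the factorization
# fails (Q is only guaranteed PSD, not PD, for arbitrary kernels).
.cholWithRidge <- function(Q) {
  base <- 1e-10 * sum(diag(Q)) / nrow(Q)
  for (mult in c(0, 1, 100, 1e4, 1e6)) {
    R <- tryCatch(chol(Q + diag(mult * base, nrow(Q))), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, ridge = mult * base))
  }
  stop("kernel operator Q is numerically singular beyond ridge capacity")
}

#' Dual quadratic form of the kernelized fit
#'
#' M = Y K' Q^{-1} K Y, computed through a symmetric factorization of Q
#' (never an explicit inverse) and symmetrized.  M is symmetric PSD (it is a
#' congruence of a PSD matrix); \code{check = TRUE} asserts the smallest
#' eigenvalue is >= -tol * ||M|| as a runtime check.
#'
#' @param K Gram matrix
#' @param y labels in \{+1, -1\}
#' @param Q regularized kernel operator from [assembleQ()]
#' @param check verify the eigenvalue bound
#' @return symmetric PSD N x N matrix
#' @export
assembleM <- function(K, y, Q, check = TRUE) {
  ch <- .cholWithRidge(Q)
  V <- backsolve(ch$R, K, transpose = TRUE)   # R^-T K
  M <- .symmetrize(crossprod(V) * tcrossprod(y))
  if (check) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    scale <- max(abs(ev), .Machine$double.eps)
    if (min(ev) < -1e-8 * scale)
      warning(sprintf("M has negative eigenvalue %.3e (scale %.3e)",
                      min(ev), scale))
  }
  attr(M, "ridge") <- ch$ridge
  M
}

#' Fit the kernelized fuzzy imbalance-aware SVM
#'
#' Memberships are computed in feature space through the Gram matrix, the
#' locality graph uses kernel-induced distances, the dual has the same
#' equality/box structure as the linear case with M in place of H, and the
#' representer coefficients are beta* = Q^{-1} K Y alpha*.  Thresholds
#' average the training decision values over each class's support vectors.
#'
#' The \code{variant} argument controls whether the threshold and decision
#' expansions carry an extra label factor y_j alongside beta_j.  Since beta*
#' already absorbs Y once, the label-free form (\code{"noY"}) is the one
#' that reduces exactly to the linear fit under the linear kernel, and is
#' the default; \code{"asPrinted"} retains the doubled label factor for
#' comparison.  The variant used is recorded in the model.
#'
#' @param ds a \linkS4class{CipDataSet} (training data)
#' @param control a [cipControl()] bundle
#' @param spec a [kernelSpec()]; default is a Gaussian kernel with the
#'   tau^2 spread heuristic
#' @param mu optional membership vector; computed in feature space from
#'   \code{control$family} when missing
#' @param variant threshold/decision expansion variant (see Details)
#' @param svRule see [recoverLinear()]
#' @param enforceRhoNonneg keep the minority margin offset nonnegative (see
#'   [fitLinearCip()])
#' @return a \linkS4class{KernelCipModel}
#' @examples
#' ds <- simulateDataset(simSpec(nPos = 60, nNeg = 10, dim = 2, seed = 3))
#' fit <- fitKernelCip(ds, cipControl(nu = 3, family = "exponential"))
#' mean(predict(fit, features(ds)) == classLabels(ds))
#' @export
fitKernelCip <- function(ds, control = cipControl(), spec = NULL, mu = NULL,
                         variant = c("noY", "asPrinted"),
                         svRule = c("interior", "all"),
                         enforceRhoNonneg = TRUE) {
  variant <- match.arg(variant)
  svRule <- match.arg(svRule)
  if (is.null(spec)) spec <- kernelSpec("rbf", sigma = tauSquared(ds@X))
  N <- nrow(ds@X)
  K <- gramMatrix(ds@X, spec = spec)
  if (is.null(mu))
    mu <- kernelMembership(K, ds@y, control$family, control$delta,
                           control$lambda)
  graph <- NULL
  if (control$eta > 0)
    graph <- kernelWithinClassGraph(K, ds@y, control$k, control$t)
  Q <- assembleQ(K, ds@y, graph, control$eta)
  M <- assembleM(K, ds@y, Q, check = FALSE)
  ub <- .dualUpperBounds(mu, ds@m1, N, control$v1, control$v2)
  dp <- new("CipDual", H = M, ub = ub, nu = control$nu, m1 = ds@m1)
  massPos <- sum(ub[.posIdx(ds@m1)])
  massNeg <- sum(ub[.negIdx(ds@m1, N)])
  if (massPos < control$nu || massNeg < control$nu) {
    lim <- if (massPos < massNeg) "positive" else "negative"
    stop(sprintf("infeasible nu = %g: limiting class is the %s class (bound mass %g)",
                 control$nu, lim, min(massPos, massNeg)))
  }
  sol <- if (enforceRhoNonneg) .solveEnforcingRho(dp) else solveDual(dp)
  alpha <- sol$alpha
  ch <- .cholWithRidge(Q)
  beta <- as.numeric(backsolve(ch$R, backsolve(ch$R, K %*% (ds@y * alpha),
                                               transpose = TRUE)))
  coefs <- if (variant == "asPrinted") beta * ds@y else beta
  g <- as.numeric(K %*% coefs)   # training decision values minus threshold
  tol <- .svTol(ub)
  isSV <- alpha > tol
  pos <- .posIdx(ds@m1)
  neg <- .negIdx(ds@m1, N)
  sv1 <- pos[isSV[pos]]
  sv2 <- neg[isSV[neg]]
  if (length(sv1) == 0L || length(sv2) == 0L)
    stop("no support vectors in the ", if (length(sv1)) "negative" else "positive",
         " class; increase nu or revisit v1/v2")
  kktInfo <- sol[intersect(names(sol), c("lambda", "residuals", "bKKT",
                                         "rhoKKT", "status", "effectiveNu"))]
  interior <- isSV & (alpha < ub - tol)
  th1 <- if (svRule == "interior") pos[interior[pos]] else sv1
  th2 <- if (svRule == "interior") neg[interior[neg]] else sv2
  if (length(th1) && length(th2)) {
    bStar <- 1 - mean(g[th1])
    rhoStar <- mean(g[th1]) - mean(g[th2]) - 2
    kktInfo$recovery <- "margin-average"
  } else {
    pt <- .primalThresholds(g, ds@m1, mu, control, control$nu)
    bStar <- pt$b
    rhoStar <- pt$rho
    kktInfo$recovery <- "primal-linesearch"
    kktInfo$bKKT <- NULL
    kktInfo$rhoKKT <- NULL
  }
  xi <- numeric(N)
  xi[pos] <- pmax(0, 1 - (g[pos] + bStar))
  xi[neg] <- pmax(0, 1 + rhoStar + (g[neg] + bStar))
  me <- .marginErrorSets(g, ds@m1, bStar, rhoStar, kktInfo)
  new("KernelCipModel",
    alpha = alpha, beta = beta, bStar = bStar, rhoStar = rhoStar,
    sv1 = as.integer(sv1), sv2 = as.integer(sv2),
    me1 = me$me1, me2 = me$me2,
    xi = xi, mu = mu, control = unclass(control),
    kkt = kktInfo,
    trainX = ds@X, kernel = unclass(spec), variant = variant, m1 = ds@m1
  )
}

#' @describeIn decisionValues kernel model: sum_j beta_j K(x, x_j) + b*
#' @export
setMethod("decisionValues", "KernelCipModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object@trainX))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         ncol(object@trainX))
  y <- c(rep(1, object@m1), rep(-1, length(object@alpha) - object@m1))
  coefs <- if (object@variant == "asPrinted") object@beta * y else object@beta
  Knew <- gramMatrix(newdata, object@trainX, structure(object@kernel,
                                                       class = "CipKernel"))
  as.numeric(Knew %*% coefs) + object@bStar
})

#' @rdname predict-LinearCipModel-method
#' @export
setMethod("predict", "KernelCipModel",
  function(object, newdata, type = c("class", "decision")) {
    type <- match.arg(type)
    d <- decisionValues(object, newdata)
    if (type == "decision") d else .signPlus(d)
  }
)
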