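#' Class means
#'
#' Arithmetic mean feature vector of each class.
#'
#' @param ds a \linkS4class{CipDataSet}
#' @return list with numeric vectors \code{pos} and \code{neg}
#' @export
classMeans <- function(ds) {
  pos <- ds@X[.posIdx(ds@m1), , drop = FALSE]
  neg <- ds@X[.negIdx(ds@m1, nrow(ds@X)), , drop = FALSE]
  list(pos = colMeans(pos), neg = colMeans(neg))
}

.ownClassDistances <- function(ds) {
  mns <- classMeans(ds)
  N <- nrow(ds@X)
  d <- numeric(N)
  pos <- .posIdx(ds@m1)
  neg <- .negIdx(ds@m1, N)
  d[pos] <- sqrt(rowSums(sweep(ds@X[pos, , drop = FALSE], 2, mns$pos)^2))
  d[neg] <- sqrt(rowSums(sweep(ds@X[neg, , drop = FALSE], 2, mns$neg)^2))
  d
}

.linearMuFromDistances <- function(d, class, delta) {
  mu <- numeric(length(d))
  for (cl in unique(class)) {
    idx <- which(class == cl)
    dmax <- max(d[idx])
    mu[idx] <- 1 - d[idx] / (dmax + delta)
  }
  mu
}

#' Linear fuzzy membership
#'
#' mu_i = 1 - ||x_i - mean(own class)|| / (max over own class of that
#' distance + delta).  The sample at its class mean gets mu = 1; the farthest
#' sample of a class gets the strictly positive floor delta / (dmax + delta).
#' The normalizing maximum is taken over the sample's own class, since the
#' membership measures importance to that class.
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param delta small positive constant keeping memberships away from zero
#'   (default 1e-6, the value used throughout the evaluation protocol).
#' @return numeric vector of memberships in (0, 1]
#' @export
linearMembership <- function(ds, delta = 1e-6) {
  .assertScalar(delta, "delta", lower = 0, strictLower = TRUE)
  .linearMuFromDistances(.ownClassDistances(ds), ds@y, delta)
}

#' Exponential fuzzy membership
#'
#' mu_i = 2 / (1 + exp(lambda ||x_i - mean(own class)||)); lambda in [0, 1]
#' sets the steepness of the decay, lambda = 0 giving mu = 1 for every
#' sample.
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param lambda decay steepness in [0, 1]
#' @return numeric vector of memberships in (0, 1]
#' @export
exponentialMembership <- function(ds, lambda) {
  .assertScalar(lambda, "lambda", lower = 0, upper = 1)
  2 / (1 + exp(lambda * .ownClassDistances(ds)))
}

#' Fuzzy membership dispatcher
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param family \code{"linear"} or \code{"exponential"}
#' @param delta linear-family floor constant
#' @param lambda exponential-family steepness (required for that family)
#' @return numeric vector of memberships in (0, 1]
#' @export
fuzzyMembership <- function(ds, family = c("linear", "exponential"),
                            delta = 1e-6, lambda = NULL) {
  family <- match.arg(family)
  if (family == "linear") linearMembership(ds, delta)
  else {
    if (is.null(lambda))
      stop("the exponential membership family requires 'lambda'")
    exponentialMembership(ds, lambda)
  }
}

#' Distance to a class mean in kernel feature space
#'
#' ||phi(x_i) - phi-mean of the class||, evaluated through the Gram matrix:
#' sqrt(K_ii - (2/|C|) sum_{j in C} K_ij + (1/|C|^2) sum_{s,t in C} K_st).
#' Radicands in [-tol, 0) (roundoff) are clamped to zero; anything below
#' -tol signals an invalid kernel matrix and is an error.
#'
#' @param K Gram matrix over the training samples
#' @param i sample index
#' @param classMembers indices of the class whose mean is used
#' @param tol clamping tolerance for negative radicands
#' @return nonnegative distance
#' @export
featureSpaceDistance <- function(K, i, classMembers,
                                 tol = 1e-8 * max(abs(diag(K)), 1)) {
  if (length(classMembers) == 0L) stop("classMembers must be nonempty")
  m <- length(classMembers)
  r <- K[i, i] - (2 / m) * sum(K[i, classMembers]) +
    sum(K[classMembers, classMembers]) / m^2
  if (r < -tol)
    stop("negative squared feature-space distance (", format(r),
         "): kernel matrix is not positive semidefinite")
  sqrt(max(r, 0))
}

.featureSpaceDistances <- function(K, y) {
  N <- length(y)
  d <- numeric(N)
  for (cl in c(1, -1)) {
    idx <- which(y == cl)
    m <- length(idx)
    Kc <- K[idx, idx, drop = FALSE]
    r <- diag(K)[idx] - 2 * rowMeans(K[idx, idx, drop = FALSE]) + mean(Kc)
    tol <- 1e-8 * max(abs(diag(K)), 1)
    if (any(r < -tol))
      stop("negative squared feature-space distance: invalid kernel matrix")
    d[idx] <- sqrt(pmax(r, 0))
  }
  d
}

#' Fuzzy membership in kernel feature space
#'
#' Applies the linear or exponential membership formula with the
#' feature-space distance to the own-class mean in place of the Euclidean
#' one.  With the linear kernel this reduces exactly to the input-space
#' membership of the same family.  The linear family's normalizing maximum
#' is taken over the own class, as in input space.
#'
#' @param K Gram matrix over the training samples
#' @param y labels in \{+1, -1\}
#' @inheritParams fuzzyMembership
#' @return numeric vector of memberships in (0, 1]
#' @export
kernelMembership <- function(K, y, family = c("linear", "exponential"),
                             delta = 1e-6, lambda = NULL) {
  family <- match.arg(family)
  d <- .featureSpaceDistances(K, y)
  if (family == "linear") {
    .assertScalar(delta, "delta", lower = 0, strictLower = TRUE)
    .linearMuFromDistances(d, y, delta)
  } else {
    if (is.null(lambda))
      stop("the exponential membership family requires 'lambda'")
    .assertScalar(lambda, "lambda", lower = 0, upper = 1)
    2 / (1 + exp(lambda * d))
  }
}
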