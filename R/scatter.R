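#' Within-class k-nearest-neighbor support
#'
#' Boolean neighbor support under the symmetric OR rule: an (i, j) edge
#' exists iff y_i = y_j and i is among the k nearest within-class neighbors
#' of j or vice versa.  Self-edges are excluded; ties in the neighbor sort
#' are broken by smaller sample index (determinism).  k is truncated to
#' class size - 1 with a warning when a class is too small.
#'
#' @param y labels in \{+1, -1\}
#' @param D2 squared pairwise distance matrix consistent with the space the
#'   graph lives in (Euclidean in input space, kernel-induced
#'   K_ii + K_jj - 2 K_ij in feature space)
#' @param k neighbor count (positive integer)
#' @return logical symmetric support matrix
#' @export
knnWithinClass <- function(y, D2, k) {
  if (k < 1) stop("k must be >= 1")
  N <- length(y)
  sup <- matrix(FALSE, N, N)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    kc <- min(k, length(idx) - 1L)
    if (kc < k)
      warning(sprintf("k = %d truncated to %d for class %+d (size %d)",
                      k, kc, cl, length(idx)))
    if (kc < 1L) next
    for (i in idx) {
      others <- setdiff(idx, i)
      ord <- others[order(D2[i, others], others)]
      sup[i, ord[seq_len(kc)]] <- TRUE
    }
  }
  sup | t(sup)
}

#' Heat-kernel weights on a neighbor support
#'
#' Raw affinities exp(-d^2/t) on supported edges, then each row divided by
#' its raw row sum, so every row with at least one within-class neighbor
#' sums to one.  Rows without edges stay all-zero.
#'
#' @param edgeSupport logical support matrix (see [knnWithinClass()])
#' @param D2 squared distance matrix
#' @param t heat-kernel width (> 0)
#' @param k,space metadata recorded on the returned graph
#' @return a \linkS4class{WithinClassGraph}
#' @export
heatWeights <- function(edgeSupport, D2, t, k = NA_integer_, space = "input") {
  .assertScalar(t, "t", lower = 0, strictLower = TRUE)
  W <- exp(-D2 / t) * edgeSupport
  rs <- rowSums(W)
  nz <- rs > 0
  W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  dimnames(W) <- dimnames(edgeSupport) <- NULL
  new("WithinClassGraph",
    W = W, edgeSupport = edgeSupport, k = as.integer(k), t = t, space = space
  )
}

#' Within-class locality graph of a dataset
#'
#' Convenience wrapper building the k-NN support and heat weights from
#' Euclidean distances in input space.
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param k neighbor count
#' @param t heat-kernel width
#' @return a \linkS4class{WithinClassGraph}
#' @export
withinClassGraph <- function(ds, k, t) {
  D2 <- .sqDistMatrix(ds@X)
  heatWeights(knnWithinClass(ds@y, D2, k), D2, t, k = k, space = "input")
}

#' Within-class locality graph in kernel feature space
#'
#' Same construction with the kernel-induced squared distance
#' K_ii + K_jj - 2 K_ij.
#'
#' @param K Gram matrix
#' @param y labels in \{+1, -1\}
#' @param k neighbor count
#' @param t heat-kernel width
#' @return a \linkS4class{WithinClassGraph}
#' @export
kernelWithinClassGraph <- function(K, y, k, t) {
  dK <- diag(K)
  D2 <- outer(dK, dK, "+") - 2 * K
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  heatWeights(knnWithinClass(y, D2, k), D2, t, k = k, space = "feature")
}

# Residual operator rows (I - W) with isolated nodes zeroed: a node with no
# within-class neighbor has nothing to preserve and contributes nothing to
# the scatter (rather than a spurious x_i x_i' term).
.residualOperator <- function(W, idx) {
  A <- diag(length(idx)) - W[idx, idx, drop = FALSE]
  iso <- rowSums(W[idx, , drop = FALSE]) == 0
  A[iso, ] <- 0
  A
}

#' Local within-class preserving scatter matrix (input space)
#'
#' S = sum over classes of X_c' (I - W_c)' (I - W_c) X_c: the accumulated
#' outer products of the residuals between each sample and the weighted
#' average of its within-class nearest neighbors.  Penalizing w' S w keeps
#' samples that are close within a class close after projection on w.
#' Symmetric and positive semidefinite by construction.
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param graph a \linkS4class{WithinClassGraph} built on \code{ds}
#' @return symmetric PSD matrix of size n x n (n = number of features)
#' @export
scatterLinear <- function(ds, graph) {
  N <- nrow(ds@X)
  S <- matrix(0, ncol(ds@X), ncol(ds@X))
  for (cl in c(1, -1)) {
    idx <- if (cl > 0) .posIdx(ds@m1) else .negIdx(ds@m1, N)
    A <- .residualOperator(graph@W, idx)
    R <- A %*% ds@X[idx, , drop = FALSE]
    S <- S + crossprod(R)
  }
  dimnames(S) <- NULL
  .symmetrize(S)
}

#' Kernel-side local within-class scatter terms
#'
#' The two N x N terms T_c = K_c (I_c - W_c)' (I_c - W_c) K_c', where K_c is
#' the N x m_c block of the Gram matrix restricted to class-c columns and
#' W_c the within-class weight block.  Their eta-weighted sum added to K
#' gives the regularized kernel operator of the kernelized fit.
#'
#' @param K Gram matrix
#' @param y labels in \{+1, -1\}
#' @param graph a \linkS4class{WithinClassGraph} built with kernel-induced
#'   distances
#' @return list with symmetric PSD matrices \code{T1} (positive class) and
#'   \code{T2} (negative class)
#' @export
scatterKernel <- function(K, y, graph) {
  if (nrow(K) != length(y) || nrow(graph@W) != length(y))
    stop("K, y and graph dimensions disagree")
  out <- list()
  for (cl in c(1, -1)) {
    idx <- which(y == cl)
    A <- .residualOperator(graph@W, idx)
    B <- A %*% t(K[, idx, drop = FALSE])   # m_c x N
    Tc <- .symmetrize(crossprod(B))
    dimnames(Tc) <- NULL
    out[[if (cl > 0) "T1" else "T2"]] <- Tc
  }
  out
}
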