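#' @import methods
NULL

#' Canonically ordered two-class dataset
#'
#' Container for a binary classification feature table in the canonical
#' ordering every fitting routine assumes: the \code{m1} positive
#' (majority/normal, label +1) samples come first, followed by the \code{m2}
#' negative (minority/abnormal, label -1) samples.  The permutation mapping
#' canonical rows back to the original input order is retained so that
#' predictions can be reported in file order.
#'
#' @slot X numeric matrix, one row per sample, one column per feature.
#' @slot y numeric vector of labels in \{+1, -1\}, positives first.
#' @slot m1 integer, number of positive (+1) samples.
#' @slot m2 integer, number of negative (-1) samples.
#' @slot featureNames character vector of feature names.
#' @slot origIndex integer vector; \code{origIndex[i]} is the row of the
#'   original input that canonical row \code{i} came from.
#' @slot meta list of optional provenance (e.g. simulation ground truth).
#'
#' @seealso [cipDataSet()], [readCipCSV()], [simulateDataset()]
#' @export
setClass("CipDataSet",
  representation(
    X = "matrix",
    y = "numeric",
    m1 = "integer",
    m2 = "integer",
    featureNames = "character",
    origIndex = "integer",
    meta = "list"
  )
)

setValidity("CipDataSet", function(object) {
  msg <- character()
  X <- object@X
  y <- object@y
  if (!is.numeric(X)) msg <- c(msg, "X must be numeric")
  if (any(!is.finite(X))) msg <- c(msg, "X contains missing or non-finite entries")
  if (length(y) != nrow(X)) msg <- c(msg, "length(y) must equal nrow(X)")
  if (!all(y %in% c(-1, 1))) msg <- c(msg, "labels must be in {+1, -1}")
  if (object@m1 < 1L || object@m2 < 1L) msg <- c(msg, "both classes must be nonempty")
  if (object@m1 + object@m2 != nrow(X)) msg <- c(msg, "m1 + m2 must equal nrow(X)")
  if (length(y) && !identical(y, c(rep(1, object@m1), rep(-1, object@m2))))
    msg <- c(msg, "rows must be canonically ordered: +1 labels first, then -1")
  if (length(object@origIndex) != nrow(X))
    msg <- c(msg, "origIndex must have one entry per row")
  if (length(msg)) msg else TRUE
})

#' Within-class k-nearest-neighbor heat-kernel graph
#'
#' Row-normalized heat-kernel affinities over within-class k-nearest-neighbor
#' edges.  \code{edgeSupport} is symmetric (edge if i is among j's neighbors
#' or vice versa, same class only); \code{W} is row-normalized and therefore
#' need not be symmetric.  Rows with no within-class neighbor are all zero.
#'
#' @slot W numeric N x N matrix of normalized affinities.
#' @slot edgeSupport logical N x N neighbor support matrix.
#' @slot k integer neighbor count used (after any truncation).
#' @slot t numeric heat-kernel width.
#' @slot space character, "input" or "feature".
#'
#' @seealso [withinClassGraph()], [heatWeights()]
#' @export
setClass("WithinClassGraph",
  representation(
    W = "matrix",
    edgeSupport = "matrix",
    k = "integer",
    t = "numeric",
    space = "character"
  )
)

setValidity("WithinClassGraph", function(object) {
  msg <- character()
  if (!identical(dim(object@W), dim(object@edgeSupport)))
    msg <- c(msg, "W and edgeSupport must have identical dimensions")
  if (any(object@W < 0)) msg <- c(msg, "W must be nonnegative")
  if (any(object@W[!object@edgeSupport] != 0))
    msg <- c(msg, "W must vanish off the edge support")
  if (!isSymmetric(object@edgeSupport)) msg <- c(msg, "edgeSupport must be symmetric")
  if (object@t <= 0) msg <- c(msg, "t must be positive")
  if (length(msg)) msg else TRUE
})

#' Dual quadratic program of the fuzzy imbalance-aware SVM
#'
#' The convex QP in the dual multipliers alpha: minimize (1/2) alpha' H alpha
#' subject to sum of alpha over each class equal to nu and the fuzzy box
#' 0 <= alpha_i <= mu_i / (v_c m_c).
#'
#' @slot H numeric N x N symmetric positive semidefinite matrix.
#' @slot ub numeric vector of per-sample upper bounds.
#' @slot nu numeric, common equality-constraint target for both classes.
#' @slot m1 integer, positives count (rows 1..m1 of H).
#'
#' @seealso [assembleLinearDual()], [solveDual()]
#' @export
setClass("CipDual",
  representation(H = "matrix", ub = "numeric", nu = "numeric", m1 = "integer")
)

setValidity("CipDual", function(object) {
  msg <- character()
  N <- nrow(object@H)
  if (ncol(object@H) != N) msg <- c(msg, "H must be square")
  if (length(object@ub) != N) msg <- c(msg, "ub must have one entry per sample")
  if (any(object@ub <= 0)) msg <- c(msg, "upper bounds must be strictly positive")
  if (object@nu <= 0) msg <- c(msg, "nu must be positive")
  if (object@m1 < 1L || object@m1 >= N) msg <- c(msg, "m1 must satisfy 1 <= m1 < N")
  if (length(msg)) msg else TRUE
})

#' Virtual parent of fitted models
#'
#' Common slots of the linear and kernel fits: dual multipliers, thresholds,
#' support-vector and margin-error index sets (canonical indexing), slacks,
#' the fuzzy memberships and hyperparameters used, and the KKT diagnostics of
#' the dual solve.
#'
#' @slot alpha numeric dual solution.
#' @slot bStar numeric primary threshold.
#' @slot rhoStar numeric secondary margin offset for the minority class.
#' @slot sv1,sv2 integer support-vector index sets per class.
#' @slot me1,me2 integer margin-error index sets per class.
#' @slot xi numeric reconstructed slack variables.
#' @slot mu numeric fuzzy memberships used in the fit.
#' @slot control list of hyperparameters (see [cipControl()]).
#' @slot kkt list of solver diagnostics (equality multipliers, residuals).
#' @export
setClass("CipModel",
  representation(
    alpha = "numeric",
    bStar = "numeric",
    rhoStar = "numeric",
    sv1 = "integer",
    sv2 = "integer",
    me1 = "integer",
    me2 = "integer",
    xi = "numeric",
    mu = "numeric",
    control = "list",
    kkt = "list",
    "VIRTUAL"
  )
)

#' Linear fit
#'
#' @slot w numeric weight vector of the separating hyperplane.
#' @slot m1 integer positives count of the training set.
#' @rdname CipModel-class
#' @export
setClass("LinearCipModel",
  contains = "CipModel",
  representation(w = "numeric", m1 = "integer")
)

#' Kernelized fit
#'
#' @slot beta numeric representer coefficients.
#' @slot trainX numeric matrix of retained training features.
#' @slot kernel list kernel specification (see [kernelSpec()]).
#' @slot variant character, "noY" or "asPrinted" threshold/decision variant.
#' @rdname CipModel-class
#' @export
setClass("KernelCipModel",
  contains = "CipModel",
  representation(
    beta = "numeric",
    trainX = "matrix",
    kernel = "list",
    variant = "character",
    m1 = "integer"
  )
)
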