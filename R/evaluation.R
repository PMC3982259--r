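#' Classification metrics for imbalanced two-class problems
#'
#' Sensitivity (positives correctly recognized), specificity (negatives
#' correctly recognized), accuracy, and the two- and three-way geometric
#' means.  Metrics with a zero denominator are returned as 0 and flagged in
#' \code{degenerate}.
#'
#' @param yTrue,yPred label vectors in \{+1, -1\}
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, \code{gmean2}, \code{gmean3}, confusion counts
#'   \code{TP}, \code{FN}, \code{TN}, \code{FP}, and \code{degenerate}
#' @examples
#' scoreClassifier(c(1, 1, 1, -1), c(1, 1, -1, -1))
#' @export
scoreClassifier <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("empty input")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (!all(c(yTrue, yPred) %in% c(-1, 1)))
    stop("labels must be in {+1, -1}")
  TP <- sum(yTrue == 1 & yPred == 1)
  FN <- sum(yTrue == 1 & yPred == -1)
  TN <- sum(yTrue == -1 & yPred == -1)
  FP <- sum(yTrue == -1 & yPred == 1)
  degen <- character()
  sens <- if (TP + FN > 0) TP / (TP + FN) else { degen <- c(degen, "sensitivity"); 0 }
  spec <- if (TN + FP > 0) TN / (TN + FP) else { degen <- c(degen, "specificity"); 0 }
  acc <- (TP + TN) / length(yTrue)
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       gmean2 = sqrt(sens * spec), gmean3 = (sens * spec * acc)^(1 / 3),
       TP = TP, FN = FN, TN = TN, FP = FP, degenerate = degen)
}

#' Default hyperparameter search grids
#'
#' The grids of the standard evaluation protocol: nu in \{1, 5, 10, ...,
#' 80\}; v1, v2 in \{0.001, 0.005, 0.01, 0.05\}; log2(eta) from -5 to 6 in
#' steps of 0.5; heat width t in \{0.5, ..., 4.0\}; neighbor count k in
#' \{3, 5, ..., 15\}; exponential-membership lambda in \{0.1, ..., 1\};
#' Gaussian spread multipliers 2^-4 ... 2^4 applied to tau^2.
#'
#' @param ... named overrides for any grid component
#' @return list of class \code{"CipGrid"}
#' @export
defaultGrid <- function(...) {
  g <- list(
    nu = c(1, seq(5, 80, by = 5)),
    v1 = c(0.001, 0.005, 0.01, 0.05),
    v2 = c(0.001, 0.005, 0.01, 0.05),
    eta = 2^seq(-5, 6, by = 0.5),
    t = seq(0.5, 4, by = 0.5),
    k = seq(3, 15, by = 2),
    lambda = seq(0.1, 1, by = 0.1),
    sigmaMult = 2^(-4:4),
    delta = 1e-6
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(g)))
  g[names(over)] <- over
  lapply(g, function(v) { stopifnot(length(v) >= 1); v })
  structure(g, class = "CipGrid")
}

# Stratified fold assignment: per-class round robin over shuffled indices,
# so every fold's class ratio is within one sample of the global ratio.
.stratifiedFolds <- function(ds, folds, seed) {
  N <- nrow(ds@X)
  assign <- integer(N)
  withSeed(seed, {
    for (cl in c(1, -1)) {
      idx <- which(ds@y == cl)
      if (length(idx) < folds)
        stop("class ", cl, " has fewer members (", length(idx),
             ") than folds (", folds, ")")
      assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

.fitAndScore <- function(train, test, control, kind, sigmaMult) {
  fit <- if (kind == "linear") fitLinearCip(train, control)
    else fitKernelCip(train, control,
                      kernelSpec("rbf", sigma = sigmaMult * tauSquared(train@X)))
  scoreClassifier(test@y, predict(fit, test@X))
}

#' Stratified cross-validated grid selection
#'
#' Exhaustive evaluation of the cartesian product of the supplied grids by
#' stratified k-fold cross-validation.  The best mean accuracy wins; ties
#' are broken by higher mean two-way G-mean, then by the deterministic
#' lexicographic order of the grid expansion.  Configurations that are
#' infeasible (nu exceeding a class's bound mass) or otherwise fail score
#' NA and are skipped.  An optional \code{budget} evaluates a seeded random
#' subset of the grid instead of the full product.
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param kind \code{"linear"} or \code{"kernel"}
#' @param grid a [defaultGrid()]-style list (use small custom grids for
#'   anything interactive; the full default product is combinatorially
#'   large)
#' @param family membership family passed to the fits
#' @param folds number of cross-validation folds
#' @param seed integer seed controlling fold assignment (and subset draw)
#' @param budget optional maximum number of configurations to evaluate
#' @return list with \code{best} (a [cipControl()]), \code{sigmaMult},
#'   \code{table} (per-configuration mean metrics)
#' @export
cvSelect <- function(ds, kind = c("linear", "kernel"), grid = defaultGrid(),
                     family = c("linear", "exponential"),
                     folds = 5, seed = 1, budget = NULL) {
  kind <- match.arg(kind)
  family <- match.arg(family)
  conf <- expand.grid(
    nu = grid$nu, v1 = grid$v1, v2 = grid$v2, eta = grid$eta,
    t = grid$t, k = grid$k,
    lambda = if (family == "exponential") grid$lambda else 0.5,
    sigmaMult = if (kind == "kernel") grid$sigmaMult else 1,
    KEEP.OUT.ATTRS = FALSE
  )
  if (!is.null(budget) && budget < nrow(conf)) {
    keep <- withSeed(seed + 1L, sort(sample(nrow(conf), budget)))
    conf <- conf[keep, , drop = FALSE]
  }
  assign <- .stratifiedFolds(ds, folds, seed)
  acc <- gm <- rep(NA_real_, nrow(conf))
  for (i in seq_len(nrow(conf))) {
    ctl <- cipControl(nu = conf$nu[i], v1 = conf$v1[i], v2 = conf$v2[i],
                      eta = conf$eta[i], k = conf$k[i], t = conf$t[i],
                      family = family, delta = grid$delta[1],
                      lambda = conf$lambda[i])
    sc <- vapply(seq_len(folds), function(f) {
      tr <- which(assign != f)
      te <- which(assign == f)
      train <- cipDataSet(ds@X[tr, , drop = FALSE], ds@y[tr],
                          featureNames = ds@featureNames)
      test <- cipDataSet(ds@X[te, , drop = FALSE], ds@y[te],
                         featureNames = ds@featureNames)
      out <- tryCatch(
        suppressWarnings(.fitAndScore(train, test, ctl, kind, conf$sigmaMult[i])),
        error = function(e) NULL
      )
      if (is.null(out)) c(NA_real_, NA_real_)
      else c(out$accuracy, out$gmean2)
    }, numeric(2))
    acc[i] <- mean(sc[1, ])
    gm[i] <- mean(sc[2, ])
  }
  ok <- which(!is.na(acc))
  if (length(ok) == 0L) stop("no feasible configuration in the grid")
  best <- ok[order(-acc[ok], -gm[ok], ok)][1]
  list(
    best = cipControl(nu = conf$nu[best], v1 = conf$v1[best],
                      v2 = conf$v2[best], eta = conf$eta[best],
                      k = conf$k[best], t = conf$t[best], family = family,
                      delta = grid$delta[1], lambda = conf$lambda[best]),
    sigmaMult = conf$sigmaMult[best],
    table = cbind(conf, meanAccuracy = acc, meanGmean2 = gm)
  )
}

#' Repeat-averaged evaluation with fixed train counts
#'
#' Repeats, \code{nRepeats} times: a stratified split drawing the requested
#' class counts for training, a fit, and test-set scoring.  Reports each
#' metric as mean (percent) with the standard deviation on the fraction
#' scale, matching the benchmark-table convention (e.g. "95.87 +/- 0.017").
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param control a [cipControl()] bundle
#' @param trainCounts integer(2): positives and negatives drawn for training
#' @param kind \code{"linear"} or \code{"kernel"}
#' @param sigmaMult Gaussian spread multiplier applied to the training
#'   tau^2 (kernel fits)
#' @param nRepeats number of independent repeats
#' @param seed integer seed; repeat r uses seed + r
#' @return object of class \code{"CipEvalReport"}: per-repeat metric matrix
#'   plus formatted mean/std summary
#' @export
repeatedExperiment <- function(ds, control, trainCounts,
                               kind = c("linear", "kernel"), sigmaMult = 1,
                               nRepeats = 10, seed = 1) {
  kind <- match.arg(kind)
  metrics <- c("sensitivity", "specificity", "accuracy", "gmean2", "gmean3")
  res <- matrix(NA_real_, nRepeats, length(metrics),
                dimnames = list(NULL, metrics))
  for (r in seq_len(nRepeats)) {
    sp <- stratifiedSplit(ds, trainCounts[1], trainCounts[2], seed = seed + r)
    if (is.null(sp$test)) stop("empty test set; reduce trainCounts")
    sc <- .fitAndScore(sp$train, sp$test, control, kind, sigmaMult)
    res[r, ] <- unlist(sc[metrics])
  }
  mn <- colMeans(res)
  sd <- apply(res, 2, stats::sd)
  structure(list(
    perRepeat = res,
    meanPercent = 100 * mn,
    sdFraction = sd,
    cells = sprintf("%.2f \u00b1 %.3f", 100 * mn, sd),
    nRepeats = nRepeats, trainCounts = trainCounts, kind = kind
  ), class = "CipEvalReport")
}

#' @export
print.CipEvalReport <- function(x, ...) {
  cat(sprintf("Repeat-averaged evaluation (%d repeats, %s fit, train %d/%d)\n",
              x$nRepeats, x$kind, x$trainCounts[1], x$trainCounts[2]))
  hdr <- c("Sensitivity", "Specificity", "Accuracy")
  cells <- x$cells[1:3]
  w <- max(nchar(c(hdr, cells))) + 2
  cat(paste(formatC(hdr, width = w), collapse = ""), "\n")
  cat(paste(formatC(cells, width = w), collapse = ""), "\n")
  invisible(x)
}

#' Fixed-width comparison table
#'
#' Formats one or more evaluation reports as the standard benchmark layout
#' (Method | Sensitivity | Specificity | Accuracy, percent with +/-).
#'
#' @param reports named list of \code{"CipEvalReport"} objects
#' @return character vector of table lines (also printed)
#' @export
formatEvalTable <- function(reports) {
  stopifnot(length(names(reports)) == length(reports))
  hdr <- c("Method", "Sensitivity", "Specificity", "Accuracy")
  rows <- lapply(names(reports), function(nm) c(nm, reports[[nm]]$cells[1:3]))
  all <- do.call(rbind, c(list(hdr), rows))
  w <- apply(nchar(all), 2, max) + 2
  lines <- apply(all, 1, function(r)
    paste(mapply(formatC, r, width = w, MoreArgs = list(flag = "-")),
          collapse = ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
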