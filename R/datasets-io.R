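#' Construct a canonically ordered dataset
#'
#' Reorders samples so that all +1 labels (the majority/normal class) precede
#' all -1 labels (the minority/abnormal class) and records the permutation.
#' The ordering within each class is preserved (stable sort).
#'
#' @param X numeric matrix or data frame of features, one row per sample.
#' @param y labels; numeric +1/-1, or any two-valued vector together with
#'   \code{positiveLabel}.
#' @param positiveLabel value of \code{y} to map to +1; required when
#'   \code{y} is not already +1/-1 coded.
#' @param featureNames optional character vector of feature names.
#' @param meta optional list of provenance carried along unchanged.
#' @return a \linkS4class{CipDataSet}
#' @examples
#' ds <- cipDataSet(matrix(rnorm(12), 6, 2), c(1, -1, 1, 1, -1, 1))
#' nPos(ds); nNeg(ds)
#' @export
cipDataSet <- function(X, y, positiveLabel = NULL, featureNames = NULL,
                       meta = list()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.null(positiveLabel)) {
    vals <- unique(y)
    if (length(vals) != 2L)
      stop("label vector must have exactly two distinct values, found ",
           length(vals))
    if (!positiveLabel %in% vals)
      stop("positiveLabel '", positiveLabel, "' not present among labels")
    y <- ifelse(y == positiveLabel, 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be coded +1/-1 (or supply 'positiveLabel')")
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite feature value at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  if (is.null(featureNames)) {
    featureNames <- colnames(X)
    if (is.null(featureNames)) featureNames <- paste0("V", seq_len(ncol(X)))
  }
  colnames(X) <- featureNames
  ord <- order(-y)  # stable: positives first, original order within class
  new("CipDataSet",
    X = X[ord, , drop = FALSE], y = y[ord],
    m1 = sum(y > 0), m2 = sum(y < 0),
    featureNames = featureNames, origIndex = as.integer(ord), meta = meta
  )
}

#' Read a labeled feature table from CSV
#'
#' Loads a header-ed delimited table, validates that every feature cell is a
#' finite real and that the label column carries exactly two values, and
#' returns the canonically ordered dataset.
#'
#' @param path path to the CSV file.
#' @param labelColumn name of the label column.
#' @param positiveLabel label value mapped to +1 (majority/normal class).
#' @param sep field delimiter.
#' @return a \linkS4class{CipDataSet}
#' @export
readCipCSV <- function(path, labelColumn, positiveLabel, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!labelColumn %in% names(df))
    stop("label column '", labelColumn, "' not found; columns are: ",
         paste(names(df), collapse = ", "))
  yraw <- df[[labelColumn]]
  feat <- df[setdiff(names(df), labelColumn)]
  for (j in seq_along(feat)) {
    v <- suppressWarnings(as.numeric(feat[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing feature cell at row %d, column '%s'",
                   bad[1], names(feat)[j]))
    feat[[j]] <- v
  }
  vals <- unique(yraw)
  if (length(vals) != 2L)
    stop("label column '", labelColumn, "' must have exactly two distinct ",
         "values, found ", length(vals))
  cipDataSet(as.matrix(as.data.frame(feat)), yraw, positiveLabel = positiveLabel)
}

#' Write a dataset to CSV
#'
#' Emits the samples in their original input order (the inverse of the
#' canonical permutation) so that a save/load round trip reproduces the file
#' layout as well as the values.
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param path output path
#' @param labelColumn name for the label column
#' @param positiveLabel,negativeLabel values written for +1 / -1
#' @export
writeCipCSV <- function(ds, path, labelColumn = "label",
                        positiveLabel = "1", negativeLabel = "-1") {
  inv <- order(ds@origIndex)
  # %.17g keeps finite doubles bit-exact through a save/load round trip
  df <- as.data.frame(lapply(as.data.frame(ds@X[inv, , drop = FALSE]),
                             function(v) sprintf("%.17g", v)))
  names(df) <- ds@featureNames
  df[[labelColumn]] <- ifelse(ds@y[inv] > 0, positiveLabel, negativeLabel)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dataset descriptors
#'
#' One-row summary in the convention used for benchmark medical tables:
#' number of positives and negatives, the (rounded) positive-to-negative
#' imbalance ratio, and the dimensionality.
#'
#' @param object a \linkS4class{CipDataSet}
#' @return a one-row \code{data.frame} with columns \code{nPos}, \code{nNeg},
#'   \code{ratio}, \code{d}.
#' @export
setMethod("describeDataSet", "CipDataSet", function(object) {
  data.frame(
    nPos = object@m1, nNeg = object@m2,
    ratio = paste0(round(object@m1 / object@m2), ":1"),
    d = ncol(object@X),
    stringsAsFactors = FALSE
  )
})

#' Stratified train/test split with fixed class counts
#'
#' Draws exactly \code{nPosTrain} positives and \code{nNegTrain} negatives
#' without replacement for the training set; the complement becomes the test
#' set.  Both outputs are canonically ordered; the draw is reproducible under
#' \code{seed} and leaves the caller's RNG stream untouched.
#'
#' @param ds a \linkS4class{CipDataSet}
#' @param nPosTrain,nNegTrain class counts requested for the training set.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}
#' @export
stratifiedSplit <- function(ds, nPosTrain, nNegTrain, seed) {
  if (nPosTrain > ds@m1 || nNegTrain > ds@m2)
    stop(sprintf("requested train counts (%d, %d) exceed class sizes (%d, %d)",
                 nPosTrain, nNegTrain, ds@m1, ds@m2))
  N <- nrow(ds@X)
  pos <- .posIdx(ds@m1)
  neg <- .negIdx(ds@m1, N)
  take <- withSeed(seed, {
    c(sample(pos, nPosTrain), sample(neg, nNegTrain))
  })
  rest <- setdiff(seq_len(N), take)
  if (length(rest) == 0L)
    warning("all samples requested for training; test set is empty")
  sub <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    cipDataSet(ds@X[idx, , drop = FALSE], ds@y[idx],
               featureNames = ds@featureNames,
               meta = c(ds@meta, list(parentIndex = idx)))
  }
  list(train = sub(take), test = sub(rest))
}

#' Per-feature standardization learned on a training set
#'
#' Centers and scales each feature by the training-set mean and standard
#' deviation, applying the same transform to an optional test set.  This is
#' OFF by default everywhere in the package: the underlying method is defined
#' on raw features and standardization is exposed only as an explicit choice.
#'
#' @param train,test \linkS4class{CipDataSet}s; \code{test} may be NULL.
#' @return list with standardized \code{train}, \code{test}, and the
#'   \code{center}/\code{scale} vectors used.
#' @export
standardizeFeatures <- function(train, test = NULL) {
  ctr <- colMeans(train@X)
  scl <- apply(train@X, 2, stats::sd)
  scl[scl == 0] <- 1
  tr <- function(ds) {
    if (is.null(ds)) return(NULL)
    X <- sweep(sweep(ds@X, 2, ctr), 2, scl, "/")
    cipDataSet(X, ds@y, featureNames = ds@featureNames, meta = ds@meta)
  }
  list(train = tr(train), test = tr(test), center = ctr, scale = scl)
}
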