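#' @rdname CipDataSet-class
#' @param object,x a \linkS4class{CipDataSet}
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @rdname CipDataSet-class
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname CipDataSet-class
#' @export
setGeneric("nPos", function(object) standardGeneric("nPos"))

#' @rdname CipDataSet-class
#' @export
setGeneric("nNeg", function(object) standardGeneric("nNeg"))

#' @rdname CipDataSet-class
#' @export
setGeneric("originalIndex", function(object) standardGeneric("originalIndex"))

#' @rdname describeDataSet
#' @export
setGeneric("describeDataSet", function(object) standardGeneric("describeDataSet"))

#' Decision values of a fitted model
#'
#' Real-valued decision scores f(x); the predicted label is sign(f) with
#' sign(0) mapped to +1 (deterministic tie-break favoring the majority
#' class).
#'
#' @param object a fitted \linkS4class{CipModel}
#' @param newdata numeric matrix of samples (rows) to score
#' @return numeric vector of decision values
#' @export
setGeneric("decisionValues", function(object, newdata) standardGeneric("decisionValues"))

#' @export
setMethod("features", "CipDataSet", function(object) object@X)

#' @export
setMethod("classLabels", "CipDataSet", function(object) object@y)

#' @export
setMethod("nPos", "CipDataSet", function(object) object@m1)

#' @export
setMethod("nNeg", "CipDataSet", function(object) object@m2)

#' @export
setMethod("originalIndex", "CipDataSet", function(object) object@origIndex)

setMethod("show", "CipDataSet", function(object) {
  cat("CipDataSet with", nrow(object@X), "samples x", ncol(object@X), "features\n")
  cat("  positives (+1, majority/normal):", object@m1, "\n")
  cat("  negatives (-1, minority/abnormal):", object@m2, "\n")
  r <- if (object@m2 > 0) round(object@m1 / object@m2) else NA
  cat("  imbalance ratio ~", paste0(r, ":1"), "\n")
})

setMethod("show", "WithinClassGraph", function(object) {
  cat("WithinClassGraph (", object@space, " space): ",
    nrow(object@W), " nodes, k = ", object@k, ", t = ", object@t, "\n",
    sep = ""
  )
  cat("  edges (directed support):", sum(object@edgeSupport), "\n")
})

setMethod("show", "CipDual", function(object) {
  N <- nrow(object@H)
  cat("CipDual: N =", N, "(", object@m1, "pos /", N - object@m1, "neg ), nu =",
      object@nu, "\n")
  cat("  class bound mass: pos", format(sum(object@ub[seq_len(object@m1)])),
      "/ neg", format(sum(object@ub[-seq_len(object@m1)])), "\n")
})

.showModel <- function(object, kind) {
  cat(kind, "\n")
  cat("  b* =", format(object@bStar), " rho* =", format(object@rhoStar), "\n")
  cat("  support vectors: ", length(object@sv1), " positive, ",
      length(object@sv2), " negative\n", sep = "")
  cat("  margin errors:   ", length(object@me1), " positive, ",
      length(object@me2), " negative\n", sep = "")
}

setMethod("show", "LinearCipModel", function(object) {
  .showModel(object, "Linear fuzzy SVM for class imbalance (FSVM-CIP)")
  cat("  w:", paste(format(object@w, digits = 4), collapse = " "), "\n")
})

setMethod("show", "KernelCipModel", function(object) {
  .showModel(object, "Kernel fuzzy SVM for class imbalance (FSVM-CIP)")
  cat("  kernel:", object@kernel$name,
      if (object@kernel$name == "rbf") paste0("(sigma = ", format(object@kernel$sigma), ")") else "",
      " threshold variant:", object@variant, "\n")
})
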