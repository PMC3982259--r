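# Run code under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                          strictLower = FALSE, strictUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strictLower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strictLower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (strictUpper && x >= upper)
    stop(sprintf("'%s' must be < %g", name, upper), call. = FALSE)
  if (!strictUpper && x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

.symmetrize <- function(M) (M + t(M)) / 2

# Squared Euclidean distances between all rows of X.
.sqDistMatrix <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

.posIdx <- function(m1) seq_len(m1)
.negIdx <- function(m1, N) seq.int(m1 + 1L, N)
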