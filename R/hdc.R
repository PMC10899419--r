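#' @import methods
#' @importFrom stats rnorm runif rbinom rpois rnbinom median var mad fft sd
#'   cor setNames wilcox.test fitted
#' @importFrom utils read.csv write.csv head modifyList
NULL

## ---- seeded substreams -----------------------------------------------------

#' Derive a deterministic integer seed for a named random substream
#'
#' All randomness in the package flows from one master seed; each hypervector
#' family (projection basis, area HVs, polarization, per-trial time HVs, ...)
#' draws from its own named substream so any component is reproducible in
#' isolation. The derived seed is a deterministic hash of `(seed, stream)`
#' kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param stream Character scalar naming the substream.
#' @return An integer seed.
#' @examples
#' streamSeed(1, "area") != streamSeed(1, "time")
#' @export
streamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  ch <- utf8ToInt(stream)
  h <- 0
  for (k in seq_along(ch)) h <- (h * 131 + ch[k]) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 2053 + 1) %% 2147483646) + 1L
}

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the generator seeded to `seed` and restores the global
#' RNG state afterwards, so seeded draws never perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- hypervector generation ------------------------------------------------

#' Random hypervectors
#'
#' Hypervectors (HVs) are dense length-`D` numeric vectors used as symbolic
#' tokens: independent random HVs in high dimension (`D` around 10^4) are
#' nearly orthogonal under cosine similarity, which is what lets bundling
#' memorize its constituents instead of averaging them away.
#'
#' `makeBipolarHV` draws i.i.d. Rademacher entries in \{-1, +1\};
#' `makeBinaryHV` draws i.i.d. uniform entries in \{0, 1\};
#' `makeUnitHV` draws i.i.d. uniform entries in \[0, 1) (the flavor used for
#' brain-area HVs).
#'
#' @param D Positive integer dimension (>= 2).
#' @param seed Optional integer seed; if given, the HV is drawn from a local
#'   RNG state and the global RNG is untouched.
#' @param n Number of hypervectors; if `n > 1` a `n x D` matrix is returned.
#' @return A numeric vector of length `D` (or an `n x D` matrix).
#' @examples
#' h <- makeBipolarHV(16, seed = 1)
#' all(h %in% c(-1, 1))
#' @export
makeBipolarHV <- function(D, seed = NULL, n = 1L) {
  checkDim(D)
  draw <- function() {
    m <- matrix(2 * rbinom(n * D, 1L, 0.5) - 1, nrow = n)
    if (n == 1L) drop(m) else m
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' @rdname makeBipolarHV
#' @export
makeBinaryHV <- function(D, seed = NULL, n = 1L) {
  checkDim(D)
  draw <- function() {
    m <- matrix(as.numeric(rbinom(n * D, 1L, 0.5)), nrow = n)
    if (n == 1L) drop(m) else m
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' @rdname makeBipolarHV
#' @export
makeUnitHV <- function(D, seed = NULL, n = 1L) {
  checkDim(D)
  draw <- function() {
    m <- matrix(runif(n * D), nrow = n)
    if (n == 1L) drop(m) else m
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

checkDim <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 2 || D != round(D))
    stop("hypervector dimension D must be a single integer >= 2, got: ",
         deparse(substitute(D)), " = ", paste(D, collapse = ","))
  invisible(as.integer(D))
}

## ---- algebra ---------------------------------------------------------------

#' Hypervector algebra: binding, bundling, cosine similarity
#'
#' Binding (`bindHV`) is component-wise multiplication; it associates two HVs,
#' is self-inverse on bipolar inputs (`bindHV(b, bindHV(b, a)) == a`), and
#' preserves similarity exactly: `cosineSim(a*c, b*c) == cosineSim(a, b)` for
#' bipolar `c`. Bundling (`bundleHV`) is component-wise addition; in high
#' dimension the sum stays measurably similar to each constituent
#' (cosine about `1/sqrt(k)` for `k` orthogonal equal-norm constituents).
#'
#' `cosineSim` returns the normalized dot product in \[-1, 1\]; if either
#' argument has zero norm it returns 0. This convention makes the first
#' iteration of adaptive training (class HVs initialized to zero) well
#' defined: an untrained class is maximally uninformative.
#'
#' @param a,b Numeric vectors of equal length.
#' @return `bindHV`/`bundleHV`: a numeric vector; `cosineSim`: a scalar.
#' @examples
#' a <- c(1, -1, 1); b <- c(1, 1, -1)
#' bindHV(a, b)           # c(1, -1, -1)
#' bundleHV(c(1, -1), c(1, 1))  # c(2, 0)
#' cosineSim(a, a)        # 1
#' @export
bindHV <- function(a, b) {
  if (length(a) != length(b))
    stop("cannot bind hypervectors of different dimensions (",
         length(a), " vs ", length(b), ")")
  a * b
}

#' @rdname bindHV
#' @export
bundleHV <- function(a, b) {
  if (length(a) != length(b))
    stop("cannot bundle hypervectors of different dimensions (",
         length(a), " vs ", length(b), ")")
  a + b
}

#' @rdname bindHV
#' @export
cosineSim <- function(a, b) {
  if (length(a) != length(b))
    stop("cosine similarity needs equal dimensions (",
         length(a), " vs ", length(b), ")")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

## Row-wise cosine similarity of matrix `M` (m x D) against vector `v`.
## Zero-norm rows (untrained classes) and zero-norm v give similarity 0.
rowCosine <- function(M, v, rowNorms = NULL) {
  nv <- sqrt(sum(v * v))
  if (nv == 0) return(numeric(nrow(M)))
  if (is.null(rowNorms)) rowNorms <- sqrt(rowSums(M * M))
  s <- as.vector(M %*% v) / nv
  out <- numeric(nrow(M))
  nz <- rowNorms > 0
  out[nz] <- s[nz] / rowNorms[nz]
  out
}
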