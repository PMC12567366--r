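#' Non-negative matrix factorization by multiplicative updates
#'
#' Decomposes a strictly non-negative spectra matrix into `X ~ W H` with
#' non-negative sample weights `W` (n x k) and component spectra `H`
#' (k x bands), minimizing squared reconstruction error with the classic
#' multiplicative update rules (which never increase the objective).
#' Initialization is seeded uniform-random, so results are reproducible.
#' Absorbance is the natural domain here: Beer--Lambert additivity makes
#' absorbing components mix linearly.
#'
#' @param x non-negative matrix or [SpectraTable-class].
#' @param k number of components (default 4).
#' @param maxIter maximum iterations.
#' @param tol relative objective-decrease tolerance for early stopping.
#' @param seed seed of the random initialization.
#' @return an [NMFResult-class].
#' @export
nmfDecompose <- function(x, k = 4L, maxIter = 500L, tol = 1e-9, seed = 1L) {
  X <- if (is(x, "SpectraTable")) spectra(x) else as.matrix(x)
  if (any(X < 0))
    stop("input has negative entries; factor absorbance (or reflectance), ",
         "not derivative/centred spectra", call. = FALSE)
  k <- as.integer(k)
  stopIfNot(k >= 1L && k <= min(dim(X)), "k must be in 1..min(dim)")
  eps <- 1e-12
  withSeed(seed, {
    W <- matrix(stats::runif(nrow(X) * k, 0.1, 1), nrow(X), k)
    H <- matrix(stats::runif(k * ncol(X), 0.1, 1), k, ncol(X))
    err <- numeric(0)
    last <- Inf
    it <- 0L
    while (it < maxIter) {
      it <- it + 1L
      H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
      W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
      e <- sum((X - W %*% H)^2)
      err <- c(err, e)
      if (is.finite(last) && last - e <= tol * max(last, eps)) break
      last <- e
    }
    new("NMFResult", W = W, H = H, k = k, errorTrace = err, iterations = it)
  })
}

setMethod("show", "NMFResult", function(object) {
  cat(sprintf("NMFResult: %d components, %d iterations, final error %.4g\n",
              object@k, object@iterations,
              object@errorTrace[length(object@errorTrace)]))
})

#' Match an NMF component against a reference spectrum
#'
#' Finds the component spectrum (row of `H`) with maximal Pearson
#' correlation to a reference -- e.g. the mean standard spectrum, to check
#' whether unmixing of leaf spectra recovers an absorber-like component.
#'
#' @param result an [NMFResult-class].
#' @param reference numeric reference spectrum (length = bands).
#' @return list with `component` (row index) and `r` (its correlation).
#' @export
matchComponent <- function(result, reference) {
  stopIfNot(length(reference) == ncol(result@H), "reference length mismatch")
  r <- apply(result@H, 1L, function(h) {
    if (stats::sd(h) == 0 || stats::sd(reference) == 0) 0
    else stats::cor(h, reference)
  })
  list(component = which.max(r), r = r[which.max(r)])
}

#' Principal component analysis with a fixed sign convention
#'
#' Centred singular value decomposition.  Signs are fixed by making the
#' largest-magnitude loading of every component positive, so score plots
#' reproduce bit-for-bit across runs.
#'
#' @param x matrix or [SpectraTable-class]; >= 2 rows.
#' @param nComponents components to retain (default: full rank).
#' @return a [PCAResult-class].
#' @export
pcaSpectra <- function(x, nComponents = NULL) {
  X <- if (is(x, "SpectraTable")) spectra(x) else as.matrix(x)
  stopIfNot(nrow(X) >= 2L, "need at least 2 rows")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  pos <- sv$d > max(dim(Xc)) * .Machine$double.eps * max(sv$d, 1)
  rank <- sum(pos)
  if (rank == 0L) stop("all rows identical: variance is zero", call. = FALSE)
  if (is.null(nComponents)) nComponents <- rank
  stopIfNot(nComponents <= rank,
            "nComponents exceeds the rank of the centred data")
  idx <- seq_len(nComponents)
  rot <- sv$v[, idx, drop = FALSE]
  flip <- vapply(idx, function(j) {
    l <- rot[, j]; sign(l[which.max(abs(l))])
  }, numeric(1))
  rot <- sweep(rot, 2L, flip, "*")
  scores <- sweep(sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], nComponents),
                  2L, flip, "*")
  varAll <- sv$d^2 / sum(sv$d^2)
  new("PCAResult", scores = scores, rotation = rot,
      varianceFraction = varAll[idx], center = ctr,
      totalComponents = as.integer(rank))
}

setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d components; explained variance %s\n",
              ncol(object@scores),
              paste(sprintf("%.1f%%", 100 * object@varianceFraction),
                    collapse = ", ")))
})
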