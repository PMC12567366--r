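# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.  All seeded stages of the package go through this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stage sub-seed from a master seed.  Stream order is part of
# the package contract: standards = 0, leaves = 1, cube = 2, cars = 3,
# cnn = 4, folds = 5.
stageSeed <- function(seed, stage) {
  offsets <- c(standards = 0L, leaves = 1L, cube = 2L, cars = 3L,
               cnn = 4L, folds = 5L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)

# Sample Pearson correlation of each column of X with y; columns with zero
# variance get r = 0 and a flag.  Used by several modules.
columnPearson <- function(X, y) {
  stopIfNot(nrow(X) >= 3L, "need at least 3 rows for correlation")
  sy <- stats::sd(y)
  stopIfNot(is.finite(sy) && sy > 0, "response has no variance")
  xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  sx <- sqrt(colSums(xc^2))
  r <- as.vector(crossprod(xc, yc)) / (sx * sqrt(sum(yc^2)))
  flagged <- sx == 0 | !is.finite(r)
  r[flagged] <- 0
  list(r = r, flagged = flagged)
}
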