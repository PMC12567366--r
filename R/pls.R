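#' Partial least squares regression (NIPALS, single response)
#'
#' Deterministic NIPALS decomposition on column-centred data (optionally
#' unit-variance scaled).  For a single response the weight vector of each
#' component is the normalized covariance `X'y` of the deflated data, so no
#' inner iteration is required.  Spectra share one physical unit, so the
#' default is centring without scaling -- standard chemometric practice.
#'
#' @param x predictor matrix (or [SpectraTable-class]), rows = samples.
#' @param y numeric response (defaults to the table's concentrations).
#' @param nComponents number of latent components; must not exceed the rank
#'   of the centred predictors.
#' @param scale logical, scale columns to unit variance.
#' @return a [PLSRModel-class].
#' @export
fitPLSR <- function(x, y = NULL, nComponents, scale = FALSE) {
  if (is(x, "SpectraTable")) {
    if (is.null(y)) y <- concentrations(x)
    x <- spectra(x)
  }
  X <- as.matrix(x)
  stopIfNot(!is.null(y) && length(y) == nrow(X), "y must match rows of x")
  nComponents <- as.integer(nComponents)
  stopIfNot(nComponents >= 1L, "need at least one component")
  xm <- colMeans(X)
  xs <- if (scale) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  if (any(xs == 0)) stop("zero-variance column under scaling", call. = FALSE)
  ym <- mean(y)
  E <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  f <- y - ym
  p <- ncol(X)
  W <- matrix(0, p, nComponents)
  P <- matrix(0, p, nComponents)
  Tm <- matrix(0, nrow(X), nComponents)
  q <- numeric(nComponents)
  ssy <- numeric(nComponents)
  for (a in seq_len(nComponents)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("deflation collapse: only ", a - 1L,
           " components are achievable", call. = FALSE)
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12)
      stop("deflation collapse: only ", a - 1L,
           " components are achievable", call. = FALSE)
    pv <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - t %*% t(pv)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t
    q[a] <- qa; ssy[a] <- qa^2 * tt
  }
  R <- W %*% solve(crossprod(P, W), diag(nComponents))
  b <- drop(R %*% q) / xs
  new("PLSRModel", nComponents = nComponents, weights = W, loadings = P,
      responseLoadings = q, scores = Tm, coefficients = b,
      intercept = ym - sum(xm * b), ssy = ssy,
      xCenter = xm, xScale = xs, yCenter = ym)
}

#' Predict from a fitted PLS model
#'
#' @param model a [PLSRModel-class].
#' @param newdata matrix with the same columns the model was fitted on.
#' @return numeric vector of predictions.
#' @export
predictPLSR <- function(model, newdata) {
  X <- as.matrix(newdata)
  stopIfNot(ncol(X) == length(model@coefficients), "column count mismatch")
  drop(X %*% model@coefficients) + model@intercept
}

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf("PLSRModel: %d components over %d predictors\n",
              object@nComponents, length(object@coefficients)))
  cat(sprintf("  explained response variance by component: %s\n",
              paste(sprintf("%.3g", object@ssy / sum(object@ssy)),
                    collapse = ", ")))
})

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with unit-norm
#' weight vectors and `SSY_a = q_a^2 t_a't_a` the response variance
#' explained by component `a`.  The mean of `VIP^2` over bands is exactly 1
#' by construction, so bands with VIP > 1 carry above-average importance.
#'
#' @param model a fitted [PLSRModel-class].
#' @return numeric vector of VIP scores, one per predictor.
#' @export
vipScores <- function(model) {
  tot <- sum(model@ssy)
  stopIfNot(tot > 0, "zero explained response variance")
  p <- nrow(model@weights)
  sqrt(p * drop(model@weights^2 %*% model@ssy) / tot)
}
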