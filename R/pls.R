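# Native partial least squares regression (NIPALS), the workhorse behind
# the PLS model family and the CARS/UVE selectors.

# Lean internal fitter: centred (optionally scaled) NIPALS for a single
# response. Returns the coefficient vector on the original scale plus an
# intercept; kept allocation-light because the selectors call it thousands
# of times.
.pls_core <- function(X, y, ncomp, scale = FALSE, max_iter = 500L, tol = 1e-6) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  xs <- rep(1, p)
  if (scale) {
    xs <- sqrt(colSums(Xc^2) / (n - 1L))
    xs[xs == 0] <- 1
    Xc <- sweep(Xc, 2L, xs, "/")
  }
  yc <- y - ym
  if (sum(yc^2) == 0) {
    # constant response: intercept-only model
    return(list(coefficients = rep(0, p), intercept = ym,
                x_mean = xm, x_scale = xs, y_mean = ym,
                weights = matrix(0, p, 0), loadings = matrix(0, p, 0),
                scores = matrix(0, n, 0), q = numeric(0), ncomp = 0L))
  }
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); qv <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    # With a single response the NIPALS inner loop has the closed-form
    # fixpoint w = X'y / ||X'y|| (u stays proportional to y under
    # deflation), so no iteration is needed; max_iter/tol are honoured as
    # degenerate-direction guards.
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < tol * .Machine$double.eps^0.5 || nw == 0) break
    w <- w / nw
    tt <- Xc %*% w
    tt2 <- sum(tt * tt)
    if (tt2 < .Machine$double.eps) break
    pv <- crossprod(Xc, tt) / tt2
    q <- sum(yc * tt) / tt2
    Xc <- Xc - tt %*% t(pv)
    yc <- yc - tt * q
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- tt; qv[a] <- q
    used <- a
  }
  if (used == 0L) stopf("pls error: no usable component (degenerate X)")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  Tm <- Tm[, seq_len(used), drop = FALSE]
  qv <- qv[seq_len(used)]
  beta_s <- W %*% solve(t(P) %*% W, qv)   # coefficients on the (scaled) centred scale
  beta <- drop(beta_s) / xs
  list(coefficients = beta, intercept = ym - sum(beta * xm),
       x_mean = xm, x_scale = xs, y_mean = ym,
       weights = W, loadings = P, scores = Tm, q = qv, ncomp = used)
}

#' Fit a PLS regression model
#'
#' NIPALS latent-variable decomposition with centred (and optionally
#' scaled) predictors and centred response; score vectors are mutually
#' orthogonal and the regression coefficient vector is exposed on the
#' original predictor scale (as required by the CARS and UVE selectors).
#'
#' @param X n x p predictor matrix.
#' @param y response vector, length n.
#' @param ncomp number of latent components (capped at min(n-1, p)).
#' @param scale autoscale predictors to unit variance.
#' @param max_iter,tol NIPALS iteration cap and convergence tolerance.
#' @return object of class `pls_model` with `coefficients`, `intercept`,
#'   `scores`, `loadings`, `weights`, `ncomp`.
#' @export
pls_fit <- function(X, y, ncomp = 2L, scale = FALSE, max_iter = 500L, tol = 1e-6) {
  X <- as_matrix(X)
  stopifnot(nrow(X) == length(y))
  fit <- .pls_core(X, as.numeric(y), as.integer(ncomp), scale = scale,
                   max_iter = as.integer(max_iter), tol = tol)
  fit$n_bands <- ncol(X)
  class(fit) <- "pls_model"
  fit
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as_matrix(newdata)
  if (ncol(X) != object$n_bands) {
    stopf("predict error: model expects %d bands, got %d", object$n_bands, ncol(X))
  }
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
coef.pls_model <- function(object, ...) object$coefficients

# k-fold cross-validated RMSE of a PLS model on (X, y); deterministic for a
# given fold assignment.
.pls_cv_rmse <- function(X, y, ncomp, folds) {
  press <- 0
  for (f in unique(folds)) {
    te <- which(folds == f)
    fit <- .pls_core(X[-te, , drop = FALSE], y[-te],
                     min(ncomp, length(y) - length(te) - 1L, ncol(X)))
    pred <- drop(X[te, , drop = FALSE] %*% fit$coefficients) + fit$intercept
    press <- press + sum((pred - y[te])^2)
  }
  sqrt(press / length(y))
}
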