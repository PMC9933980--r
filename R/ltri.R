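# Low Temperature Response Index: PCA-coefficient chain over the six
# standardized physiological markers (SPAD, SS, MDA, CAT, POD, SOD).

#' Standardize a marker panel
#'
#' Column-wise z-scores with the n-1 (sample) standard deviation; the
#' centring and scaling constants are retained so new samples can be scored
#' on the same scale.
#'
#' @param panel n x p numeric matrix or data.frame.
#' @return object of class `standardized_panel`: `Z` (z-scores), `center`,
#'   `scale`.
#' @export
standardize <- function(panel) {
  X <- as_matrix(panel)
  if (nrow(X) < 2L) stopf("standardize error: need at least 2 rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  const <- which(scl == 0)
  if (length(const)) {
    nm <- colnames(X)[const] %||% as.character(const)
    stopf("standardize error: constant column(s): %s", paste(nm, collapse = ", "))
  }
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  structure(list(Z = Z, center = ctr, scale = scl), class = "standardized_panel")
}

#' Apply a stored standardization to new data
#' @param standardizer a `standardized_panel`.
#' @param newdata matrix/data.frame with the same columns.
#' @return z-score matrix.
#' @export
apply_standardizer <- function(standardizer, newdata) {
  X <- as_matrix(newdata)
  sweep(sweep(X, 2L, standardizer$center), 2L, standardizer$scale, "/")
}

#' Principal component analysis on the correlation matrix
#'
#' Eigendecomposition of the p x p correlation matrix of the standardized
#' panel. Loadings are reported on the correlation scale (eigenvector times
#' sqrt(eigenvalue)), so each loading column has squared norm equal to its
#' eigenvalue and eigenvalues sum to p. Component signs are fixed so the
#' largest-|loading| entry of each column is positive.
#'
#' @param Z a `standardized_panel` or an n x p matrix of z-scores.
#' @return object of class `pca_result`: `eigenvalues` (descending),
#'   `loadings` (p x p, correlation scale), `vc` (percent variance
#'   contribution), `cvc` (cumulative percent).
#' @export
pca_correlation <- function(Z) {
  if (inherits(Z, "standardized_panel")) Z <- Z$Z
  Z <- as_matrix(Z)
  R <- cor(Z)
  if (any(!is.finite(R))) stopf("pca error: non-finite correlations")
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$values
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  loadings <- vec %*% diag(sqrt(pmax(lambda, 0)), nrow = length(lambda))
  rownames(loadings) <- colnames(Z)
  colnames(loadings) <- paste0("Y", seq_along(lambda))
  p <- ncol(Z)
  structure(list(eigenvalues = lambda, loadings = loadings,
                 vc = 100 * lambda / p, cvc = cumsum(100 * lambda / p)),
            class = "pca_result")
}

#' Select principal components to retain
#'
#' @param pca a `pca_result` (or list with `eigenvalues`, `cvc`).
#' @param rule `"eigenvalue_gt_1"` (Kaiser rule, the default), `"top_k"`,
#'   or `"cvc_threshold"`.
#' @param k number of components for `"top_k"`.
#' @param threshold cumulative-percent threshold for `"cvc_threshold"`.
#' @return integer indices of the retained components, in order.
#' @export
select_components <- function(pca, rule = c("eigenvalue_gt_1", "top_k", "cvc_threshold"),
                              k = NULL, threshold = NULL) {
  rule <- match.arg(rule)
  retained <- switch(rule,
    eigenvalue_gt_1 = which(pca$eigenvalues > 1),
    top_k = seq_len(k),
    cvc_threshold = seq_len(which(pca$cvc >= threshold)[1])
  )
  if (length(retained) == 0L || anyNA(retained)) {
    stopf("component selection error: no component retained under rule '%s'", rule)
  }
  retained
}

#' Linear combination coefficients of the retained components
#'
#' Divides each retained loading column by the square root of its
#' eigenvalue, recovering the unit eigenvector: the coefficients of the
#' component score expressed in the standardized markers.
#'
#' @param loadings p x m correlation-scale loading matrix (or `pca_result`).
#' @param eigenvalues eigenvalues matching the loading columns.
#' @param retained indices of components to keep (default all columns).
#' @return p x length(retained) coefficient matrix.
#' @export
linear_combination_coefficients <- function(loadings, eigenvalues = NULL, retained = NULL) {
  if (inherits(loadings, "pca_result")) {
    eigenvalues <- loadings$eigenvalues
    loadings <- loadings$loadings
  }
  retained <- retained %||% seq_len(ncol(loadings))
  lam <- eigenvalues[retained]
  if (any(lam <= 0)) stopf("lcc error: retained eigenvalues must be positive")
  lcc <- sweep(loadings[, retained, drop = FALSE], 2L, sqrt(lam), "/")
  colnames(lcc) <- colnames(loadings)[retained]
  lcc
}

#' Composite score coefficients
#'
#' Variance-contribution-weighted combination of the retained components'
#' linear combination coefficients: csc_i = sum_j lcc_ij * VC_j / CVC_m.
#'
#' @param lcc p x m coefficient matrix.
#' @param vc variance contributions (percent) of the retained components.
#' @param cvc_m cumulative contribution (percent); default `sum(vc)`.
#' @return p-vector of composite coefficients.
#' @export
composite_coefficients <- function(lcc, vc, cvc_m = sum(vc)) {
  if (cvc_m == 0) stopf("composite error: cumulative variance contribution is zero")
  stopifnot(ncol(lcc) == length(vc))
  drop(lcc %*% vc) / cvc_m
}

#' Normalize composite coefficients to index weights
#'
#' Sign-preserving percentage normalization: each coefficient divided by
#' the sum of absolute values, so the absolute weights sum to one.
#'
#' @param csc composite coefficient vector.
#' @return weight vector with `sum(abs(weights)) == 1`.
#' @export
normalize_coefficients <- function(csc) {
  s <- sum(abs(csc))
  if (s == 0) stopf("normalization error: all-zero composite coefficients")
  csc / s
}

#' Score samples on the index
#'
#' ltri = sum_i weights_i * z_i with z-scores from the stored
#' standardization of the fitting panel. Lower values indicate greater
#' low-temperature damage.
#'
#' @param records data.frame containing the marker columns `X1`..`X6` (or
#'   whatever names the standardizer carries).
#' @param weights normalized coefficient vector.
#' @param standardizer the `standardized_panel` the weights were built on.
#' @return `records` with an `ltri` column appended.
#' @export
compute_ltri <- function(records, weights, standardizer) {
  vars <- names(standardizer$center)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols)) {
    stopf("ltri error: records lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  panel <- records[, vars, drop = FALSE]
  if (anyNA(panel)) {
    bad <- which(is.na(as_matrix(panel)), arr.ind = TRUE)
    stopf("ltri error: missing value(s), e.g. sample %d variable %s",
          bad[1, 1], vars[bad[1, 2]])
  }
  Z <- apply_standardizer(standardizer, panel)
  records$ltri <- drop(Z %*% weights)
  records
}

#' Build the full index from a marker panel
#'
#' Runs the complete chain: standardize, correlation PCA, Kaiser retention,
#' linear combination coefficients, variance-weighted composite,
#' sign-preserving normalization, and sample scoring.
#'
#' @param panel n x 6 marker matrix or data.frame (columns X1..X6).
#' @param rule component-retention rule, see [select_components()].
#' @param k,threshold passed to [select_components()].
#' @return object of class `ltri_model`: `pca`, `retained`, `lcc`, `csc`,
#'   `weights`, `standardizer`, `scores`.
#' @export
build_ltri <- function(panel, rule = "eigenvalue_gt_1", k = NULL, threshold = NULL) {
  std <- standardize(panel)
  pca <- pca_correlation(std)
  retained <- select_components(pca, rule, k = k, threshold = threshold)
  lcc <- linear_combination_coefficients(pca$loadings, pca$eigenvalues, retained)
  csc <- composite_coefficients(lcc, pca$vc[retained])
  weights <- normalize_coefficients(csc)
  structure(list(pca = pca, retained = retained, lcc = lcc, csc = csc,
                 weights = weights, standardizer = std,
                 scores = drop(std$Z %*% weights)),
            class = "ltri_model")
}

#' Published reference tables for the index chain
#'
#' Loads the shipped fixture holding the reported eigenvalue/variance table
#' and factor-loading table of the six-marker correlation PCA (the worked
#' example the coefficient chain is validated against).
#'
#' @return list with `variance` (component, eigenvalue, vc, cvc) and
#'   `loadings` (6 x 2 matrix, rows X1..X6).
#' @export
ltri_reference <- function() {
  vpath <- system.file("extdata", "pca_variance_reference.csv", package = "frostspec")
  lpath <- system.file("extdata", "pca_loadings_reference.csv", package = "frostspec")
  variance <- read.csv(vpath)
  ltab <- read.csv(lpath)
  loadings <- as.matrix(ltab[, c("Y1", "Y2")])
  rownames(loadings) <- ltab$variable
  list(variance = variance, loadings = loadings)
}

#' Render index weights as an equation string
#' @param weights named weight vector.
#' @param lhs left-hand-side label.
#' @param digits decimals shown.
#' @return single string such as `"LTRI=0.081X1+0.146X2-..."`.
#' @export
ltri_equation <- function(weights, lhs = "LTRI", digits = 3L) {
  nm <- names(weights) %||% paste0("X", seq_along(weights))
  terms <- sprintf("%+.*f%s", digits, weights, nm)
  eq <- paste(terms, collapse = "")
  paste0(lhs, "=", sub("^\\+", "", eq))
}
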