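# Wavelength selection: successive projections algorithm (SPA), competitive
# adaptive reweighted sampling (CARS) and uninformative variable
# elimination (UVE), each returning a reproducible band_subset.

#' Band subset container
#'
#' @param indices sorted band positions (1-based).
#' @param wavelengths wavelengths of the retained bands (nm), if known.
#' @param method selector that produced the subset.
#' @param params method parameters.
#' @param diagnostics method-specific traces.
#' @return object of class `band_subset`.
#' @export
band_subset <- function(indices, wavelengths = NULL,
                        method = c("NONE", "SPA", "CARS", "UVE"),
                        params = list(), diagnostics = NULL) {
  method <- match.arg(method)
  indices <- sort(unique(as.integer(indices)))
  structure(list(indices = indices, wavelengths = wavelengths,
                 method = method, params = params, diagnostics = diagnostics),
            class = "band_subset")
}

#' Selector configuration
#'
#' Defaults follow the published parameterization: SPA searches chain
#' lengths 1-30 from 20 candidate start bands; CARS runs 300 Monte Carlo
#' iterations with 10-fold cross-validation and at most 10 PLS components;
#' UVE uses 5 PLS components, as many appended noise variables as real
#' bands, and a 0.99 reliability cutoff.
#'
#' @param spa_min,spa_max minimal/maximal SPA chain length.
#' @param spa_starts number of random start bands evaluated.
#' @param spa_val_fraction validation fraction for SPA chain scoring.
#' @param cars_runs Monte Carlo sampling iterations.
#' @param cars_folds cross-validation folds scoring each CARS subset.
#' @param cars_max_comp PLS component cap inside CARS.
#' @param cars_subset_frac calibration fraction drawn per iteration.
#' @param uve_comp PLS components inside UVE.
#' @param uve_noise_vars appended noise variables (default: one per band).
#' @param uve_cutoff reliability-quantile cutoff in (0, 1].
#' @param uve_noise_scale noise magnitude relative to mean |X|.
#' @param uve_mc_resamples if set, replaces leave-one-out with this many
#'   Monte Carlo 80% resamples.
#' @param seed selector seed.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(spa_min = 1L, spa_max = 30L, spa_starts = 20L,
                             spa_val_fraction = 0.3,
                             cars_runs = 300L, cars_folds = 10L,
                             cars_max_comp = 10L, cars_subset_frac = 0.8,
                             uve_comp = 5L, uve_noise_vars = NULL,
                             uve_cutoff = 0.99, uve_noise_scale = 1e-10,
                             uve_mc_resamples = NULL, seed = 1L) {
  if (uve_cutoff <= 0 || uve_cutoff > 1) stopf("selection config error: cutoff must be in (0, 1]")
  structure(list(spa_min = as.integer(spa_min), spa_max = as.integer(spa_max),
                 spa_starts = as.integer(spa_starts), spa_val_fraction = spa_val_fraction,
                 cars_runs = as.integer(cars_runs), cars_folds = as.integer(cars_folds),
                 cars_max_comp = as.integer(cars_max_comp), cars_subset_frac = cars_subset_frac,
                 uve_comp = as.integer(uve_comp), uve_noise_vars = uve_noise_vars,
                 uve_cutoff = uve_cutoff, uve_noise_scale = uve_noise_scale,
                 uve_mc_resamples = uve_mc_resamples, seed = as.integer(seed)),
            class = "selection_config")
}

# One SPA chain: starting from column `start`, repeatedly append the column
# with the largest norm after projection onto the orthogonal complement of
# the selected columns (sequential Gram-Schmidt deflation).
spa_chain <- function(X, start, k_max) {
  B <- ncol(X)
  chain <- integer(k_max)
  chain[1L] <- start
  proj <- X
  current <- start
  for (k in seq_len(k_max - 1L)) {
    v <- proj[, current]
    vv <- sum(v^2)
    if (vv < .Machine$double.eps) break
    proj <- proj - v %*% (crossprod(v, proj) / vv)
    norms <- colSums(proj^2)
    norms[chain[seq_len(k)]] <- -Inf
    nxt <- which.max(norms)
    if (norms[nxt] <= .Machine$double.eps) break
    chain[k + 1L] <- nxt
    current <- nxt
  }
  chain[chain != 0L]
}

#' Successive projections algorithm
#'
#' Builds candidate chains of minimally collinear bands by orthogonal
#' projection from each of `spa_starts` random start bands, then scores
#' every (start, chain length) candidate by the RMSE of a multiple linear
#' regression on a held-out validation split and returns the best chain.
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param config [selection_config()].
#' @return `band_subset` with the RMSE-vs-length trace in `diagnostics`.
#' @export
spa_select <- function(X, y, config = selection_config()) {
  X <- as_matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); B <- ncol(X)
  with_seed(config$seed, {
    n_val <- max(1L, round(config$spa_val_fraction * n))
    val <- sample.int(n, n_val)
    cal <- setdiff(seq_len(n), val)
    k_max <- min(config$spa_max, B, length(cal) - 1L)
    k_min <- max(1L, config$spa_min)
    starts <- if (config$spa_starts >= B) seq_len(B) else sort(sample.int(B, config$spa_starts))
    Xcal <- X[cal, , drop = FALSE]
    best <- list(rmse = Inf, bands = integer())
    trace <- expand.grid(start = starts, k = k_min:k_max, KEEP.OUT.ATTRS = FALSE)
    trace$rmse <- NA_real_
    row <- 0L
    for (s in starts) {
      chain <- spa_chain(Xcal, s, k_max)
      for (k in k_min:k_max) {
        row <- row + 1L
        if (k > length(chain)) next  # rank deficiency truncated the chain
        bands <- chain[seq_len(k)]
        Xi <- cbind(1, Xcal[, bands, drop = FALSE])
        fit <- lm.fit(Xi, y[cal])
        pred <- drop(cbind(1, X[val, bands, drop = FALSE]) %*% fit$coefficients)
        if (anyNA(pred)) next
        rmse <- sqrt(mean((pred - y[val])^2))
        trace$rmse[trace$start == s & trace$k == k] <- rmse
        if (rmse < best$rmse) best <- list(rmse = rmse, bands = bands)
      }
    }
    band_subset(best$bands, wavelengths_of(X)[sort(best$bands)], "SPA",
                params = list(min = k_min, max = k_max, starts = length(starts),
                              seed = config$seed),
                diagnostics = list(rmse_trace = trace, best_rmse = best$rmse))
  })
}

#' CARS exponentially decreasing retention schedule
#'
#' Retention ratio r_i = a * exp(-k * i) with endpoints fixed so that
#' r_1 = 1 (all bands eligible) and the final retained count is 2.
#'
#' @param n_bands number of bands B.
#' @param runs Monte Carlo iterations N.
#' @return data.frame with `iteration`, `ratio`, `n_retained`.
#' @export
cars_schedule <- function(n_bands, runs) {
  i <- seq_len(runs)
  k <- log(n_bands / 2) / (runs - 1)
  ratio <- exp(k * (1 - i))
  data.frame(iteration = i, ratio = ratio,
             n_retained = pmax(2L, as.integer(round(ratio * n_bands))))
}

#' Competitive adaptive reweighted sampling
#'
#' Each Monte Carlo iteration fits PLS on a random calibration subset,
#' weights bands by normalized |regression coefficient|, enforces the
#' exponentially decreasing retention count, then resamples within it
#' proportionally to the weights (adaptive reweighted sampling). Every
#' iteration's surviving subset is scored by cross-validated RMSE and the
#' minimizer is returned.
#'
#' @inheritParams spa_select
#' @return `band_subset` with retained-count and RMSE paths in
#'   `diagnostics`.
#' @export
cars_select <- function(X, y, config = selection_config()) {
  X <- as_matrix(X); y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  sched <- cars_schedule(B, config$cars_runs)
  with_seed(config$seed, {
    folds <- sample(rep_len(seq_len(config$cars_folds), n))
    keep <- seq_len(B)
    path_rmse <- rep(NA_real_, config$cars_runs)
    path_n <- integer(config$cars_runs)
    sets <- vector("list", config$cars_runs)
    for (i in seq_len(config$cars_runs)) {
      sub <- sample.int(n, max(2L, round(config$cars_subset_frac * n)))
      ncomp <- min(config$cars_max_comp, length(keep), length(sub) - 1L)
      fit <- .pls_core(X[sub, keep, drop = FALSE], y[sub], ncomp)
      w <- abs(fit$coefficients)
      if (sum(w) == 0) w <- rep(1, length(keep))
      w <- w / sum(w)
      n_keep <- min(sched$n_retained[i], length(keep))
      top <- keep[order(w, decreasing = TRUE)[seq_len(n_keep)]]
      w_top <- w[match(top, keep)]
      # adaptive reweighted sampling: weighted draw with replacement,
      # unique survivors form the next band set
      draw <- unique(top[sample.int(length(top), n_keep, replace = TRUE,
                                    prob = w_top / sum(w_top))])
      if (length(draw) < 2L) draw <- top[seq_len(min(2L, length(top)))]
      keep <- sort(draw)
      path_n[i] <- length(keep)
      sets[[i]] <- keep
      cv_comp <- min(config$cars_max_comp, length(keep))
      path_rmse[i] <- .pls_cv_rmse(X[, keep, drop = FALSE], y, cv_comp, folds)
    }
    best_i <- which.min(path_rmse)
    band_subset(sets[[best_i]], wavelengths_of(X)[sets[[best_i]]], "CARS",
                params = list(runs = config$cars_runs, folds = config$cars_folds,
                              max_comp = config$cars_max_comp,
                              subset_frac = config$cars_subset_frac,
                              seed = config$seed),
                diagnostics = list(schedule = sched, n_retained = path_n,
                                   rmse = path_rmse, best_iteration = best_i))
  })
}

#' Uninformative variable elimination
#'
#' Appends low-magnitude noise variables to the spectra, collects PLS
#' regression coefficients over leave-one-out (or Monte Carlo) resamples,
#' and computes per-variable reliability c_j = mean(b_j) / sd(b_j). Real
#' bands are retained when |c_j| exceeds the cutoff quantile of |c| over
#' the noise variables.
#'
#' @inheritParams spa_select
#' @return `band_subset` with reliabilities and the threshold in
#'   `diagnostics`.
#' @export
uve_select <- function(X, y, config = selection_config()) {
  X <- as_matrix(X); y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  nv <- as.integer(config$uve_noise_vars %||% B)
  with_seed(config$seed, {
    noise <- matrix(runif(n * nv), n, nv) * config$uve_noise_scale * mean(abs(X))
    Z <- cbind(X, noise)
    resamples <- if (is.null(config$uve_mc_resamples)) {
      lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
    } else {
      lapply(seq_len(config$uve_mc_resamples),
             function(i) sample.int(n, max(2L, round(0.8 * n))))
    }
    coefs <- matrix(NA_real_, length(resamples), B + nv)
    for (r in seq_along(resamples)) {
      idx <- resamples[[r]]
      ncomp <- min(config$uve_comp, length(idx) - 1L, B + nv)
      coefs[r, ] <- .pls_core(Z[idx, , drop = FALSE], y[idx], ncomp)$coefficients
    }
    mu <- colMeans(coefs)
    sdv <- apply(coefs, 2L, sd)
    c_rel <- ifelse(sdv == 0, ifelse(mu == 0, 0, Inf), mu / sdv)
    # (n+1)p plotting-position quantile: under a null response a real
    # variable then exceeds the threshold with probability 1 - cutoff
    thr <- quantile(abs(c_rel[(B + 1L):(B + nv)]), config$uve_cutoff,
                    names = FALSE, type = 6)
    retained <- which(abs(c_rel[seq_len(B)]) > thr)
    band_subset(retained, wavelengths_of(X)[retained], "UVE",
                params = list(comp = config$uve_comp, noise_vars = nv,
                              cutoff = config$uve_cutoff, seed = config$seed),
                diagnostics = list(reliability = c_rel[seq_len(B)],
                                   noise_reliability = c_rel[(B + 1L):(B + nv)],
                                   threshold = thr))
  })
}

#' Restrict a spectrum matrix to a band subset
#'
#' @param X samples x bands matrix.
#' @param subset a `band_subset` or integer index vector; a NONE subset
#'   returns `X` unchanged.
#' @return reduced matrix, column order preserved.
#' @export
apply_subset <- function(X, subset) {
  X <- as_matrix(X)
  if (inherits(subset, "band_subset")) {
    if (subset$method == "NONE") return(X)
    idx <- subset$indices
  } else idx <- sort(unique(as.integer(subset)))
  if (length(idx) == 0L) stopf("subset error: empty band subset")
  if (any(idx < 1L | idx > ncol(X))) stopf("subset error: index out of range [1, %d]", ncol(X))
  out <- X[, idx, drop = FALSE]
  wl <- wavelengths_of(X)
  if (!is.null(wl)) out <- set_wavelengths(out, wl[idx])
  out
}

#' Serialize a band subset to JSON
#' @param subset a `band_subset`.
#' @param path output file.
#' @export
write_band_subset <- function(subset, path) {
  jsonlite::write_json(
    list(method = subset$method, params = subset$params,
         indices = subset$indices, wavelengths = subset$wavelengths),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a band subset from JSON
#' @param path file written by [write_band_subset()].
#' @return `band_subset`.
#' @export
read_band_subset <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  band_subset(x$indices, x$wavelengths, x$method, as.list(x$params))
}
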