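# Cross-validation protocol, R2/RMSE/RPD metrics, and the
# (index x band-method x family) model grid runner.

#' Make a k-fold cross-validation plan
#'
#' Random partition into k folds. The first k-1 folds take ceiling(n/k)
#' samples and the last fold the remainder, so that n = 192, k = 5 yields
#' four folds of 39 and one of 36; the equal-size large folds serve as the
#' evaluated repeats (test 39 / train 153, averaged over 4 repeats). When
#' the remainder is zero all k folds are evaluated.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n).
#' @param seed partition seed.
#' @return object of class `cv_plan`: `folds` (list of index vectors),
#'   `evaluated` (fold numbers used as test repeats), `n`, `k`, `seed`.
#' @export
make_cv_plan <- function(n, k = 5L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < k || k < 2L) stopf("cv plan error: need n >= k >= 2 (got n=%d, k=%d)", n, k)
  big <- ceiling(n / k)
  sizes <- if ((k - 1L) * big < n) {
    c(rep(big, k - 1L), n - (k - 1L) * big)
  } else {
    # near-equal fallback when k-1 big folds would exhaust the samples
    cnt <- rep(n %/% k, k)
    if (n %% k) cnt[seq_len(n %% k)] <- cnt[seq_len(n %% k)] + 1L
    cnt
  }
  perm <- with_seed(seed, sample.int(n))
  folds <- split(perm, rep.int(seq_len(k), times = sizes))
  names(folds) <- NULL
  evaluated <- which(sizes == max(sizes))
  structure(list(folds = folds, evaluated = evaluated, n = n, k = k,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Determination coefficient and RMSE
#'
#' R2 = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2) with the mean taken
#' over the evaluated set, and RMSE = sqrt(mean((yhat - y)^2)).
#'
#' @param y_true measured values.
#' @param y_pred predicted values, same length (>= 2).
#' @return list with `r2` and `rmse`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stopf("metrics error: zero variance in measured values; R2 undefined")
  sse <- sum((y_pred - y_true)^2)
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / length(y_true)))
}

#' Relative predictive deviation
#'
#' RPD = 1 / sqrt(1 - Rp2); on any evaluated set this equals the
#' (population) standard deviation of the measured values divided by the
#' RMSE of prediction.
#'
#' @param rp2 prediction determination coefficient, < 1.
#' @return RPD value.
#' @export
compute_rpd <- function(rp2) {
  if (rp2 >= 1) stopf("rpd error: Rp2 must be < 1")
  1 / sqrt(1 - rp2)
}

# Fit + evaluate one grid cell on one evaluated repeat.
eval_cell_fold <- function(family, model_params, seed, Xtr, ytr, Xte, yte,
                           val_fraction = 0.2) {
  spec <- regressor_spec(family, model_params[[family]] %||% list(), seed = seed)
  model <- fit_regressor(spec, Xtr, ytr)
  cal <- compute_metrics(ytr, predict(model, Xtr))
  tst <- compute_metrics(yte, predict(model, Xte))
  # inner 80/20 refit supplies the validation RMSE
  n_tr <- nrow(Xtr)
  inner_val <- with_seed(seed + 1L, sample.int(n_tr, max(2L, round(val_fraction * n_tr))))
  inner_model <- fit_regressor(spec, Xtr[-inner_val, , drop = FALSE], ytr[-inner_val])
  rmsev <- compute_metrics(ytr[inner_val], predict(inner_model, Xtr[inner_val, , drop = FALSE]))$rmse
  c(Rc2 = cal$r2, RMSEC = cal$rmse, RMSEV = rmsev,
    Rp2 = tst$r2, RMSEP = tst$rmse)
}

#' Run the model-comparison grid
#'
#' One result row per (index, band method, family): bands are selected on
#' the calibration partition (per evaluated repeat, or once over all
#' samples with `selection = "once"`), each family is fitted on the
#' calibration fold and scored on the test fold, and metrics are averaged
#' over the evaluated repeats. The full scope of 7 indices x 4 band
#' methods x 6 families yields 168 rows.
#'
#' @param spectra samples x bands predictor matrix.
#' @param targets data.frame (or matrix) of response columns; `indices`
#'   names the columns to model.
#' @param indices character vector of target names.
#' @param band_methods subset of `c("NONE", "SPA", "CARS", "UVE")`.
#' @param families subset of the six model families.
#' @param cv_plan a [make_cv_plan()] for `nrow(spectra)`.
#' @param sel_config [selection_config()] for the selectors.
#' @param model_params named list of per-family parameter overrides.
#' @param selection `"per_fold"` (leakage-safe refit per repeat) or
#'   `"once"` (single selection on all samples).
#' @param seed base seed for cell-level randomness.
#' @return data.frame of class `grid_result` with one row per cell and
#'   attributes `best` (per-index argmax by Rp2, ties broken by RMSEP) and
#'   `failures`.
#' @export
run_grid <- function(spectra, targets, indices = colnames(targets),
                     band_methods = c("NONE", "SPA", "CARS", "UVE"),
                     families = model_families,
                     cv_plan = make_cv_plan(nrow(spectra)),
                     sel_config = selection_config(),
                     model_params = list(),
                     selection = c("per_fold", "once"),
                     seed = 1L) {
  selection <- match.arg(selection)
  X <- as_matrix(spectra)
  targets <- as.data.frame(targets)
  stopifnot(nrow(X) == nrow(targets), all(indices %in% names(targets)))
  results <- list()
  failures <- list()
  for (index in indices) {
    y <- as.numeric(targets[[index]])
    for (bm in band_methods) {
      sel_seed <- derive_seed(seed, paste(index, bm))
      subset_once <- NULL
      if (selection == "once") {
        subset_once <- tryCatch(select_bands(X, y, bm, sel_config, sel_seed),
                                error = function(e) e)
        if (inherits(subset_once, "error")) {
          failures[[paste(index, bm, "selection", sep = "-")]] <- conditionMessage(subset_once)
          next
        }
      }
      for (family in families) {
        cell <- tryCatch({
          mets <- NULL; n_bands <- integer()
          for (f in cv_plan$evaluated) {
            te <- cv_plan$folds[[f]]
            tr <- setdiff(seq_len(nrow(X)), te)
            sub <- subset_once %||%
              select_bands(X[tr, , drop = FALSE], y[tr], bm, sel_config, sel_seed)
            Xs <- apply_subset(X, sub)
            m <- eval_cell_fold(family, model_params,
                                derive_seed(seed, paste(index, bm, family, f)),
                                Xs[tr, , drop = FALSE], y[tr],
                                Xs[te, , drop = FALSE], y[te])
            mets <- rbind(mets, m)
            n_bands <- c(n_bands, ncol(Xs))
          }
          avg <- colMeans(mets)
          data.frame(index = index, band_method = bm, family = family,
                     n_bands = round(mean(n_bands)),
                     Rc2 = avg[["Rc2"]], RMSEC = avg[["RMSEC"]],
                     RMSEV = avg[["RMSEV"]], Rp2 = avg[["Rp2"]],
                     RMSEP = avg[["RMSEP"]],
                     RPD = if (avg[["Rp2"]] < 1) compute_rpd(avg[["Rp2"]]) else Inf,
                     seed = seed, stringsAsFactors = FALSE)
        }, error = function(e) e)
        if (inherits(cell, "error")) {
          failures[[paste(index, bm, family, sep = "-")]] <- conditionMessage(cell)
        } else {
          results[[length(results) + 1L]] <- cell
        }
      }
    }
  }
  if (length(results) == 0L) {
    stopf("grid error: every cell failed; first failure: %s",
          if (length(failures)) failures[[1]] else "unknown")
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  best <- do.call(rbind, lapply(split(out, out$index), function(d) {
    d <- d[order(-d$Rp2, d$RMSEP), ]
    d[1L, ]
  }))
  rownames(best) <- NULL
  attr(out, "best") <- best
  attr(out, "failures") <- failures
  class(out) <- c("grid_result", class(out))
  out
}

# Dispatch a band-selection method by name.
select_bands <- function(X, y, method, config = selection_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  switch(toupper(method),
    NONE = band_subset(seq_len(ncol(X)), wavelengths_of(X), "NONE"),
    SPA = spa_select(X, y, config),
    CARS = cars_select(X, y, config),
    UVE = uve_select(X, y, config),
    stopf("unknown band-selection method '%s'", method))
}

#' Render a grid result as a markdown report
#' @param grid a `grid_result`.
#' @return character vector of report lines.
#' @export
grid_report <- function(grid) {
  best <- attr(grid, "best")
  lines <- c("# Model grid report", "",
             sprintf("%d cells evaluated.", nrow(grid)), "",
             "## Best model per index (by Rp2)", "")
  for (i in seq_len(nrow(best))) {
    b <- best[i, ]
    lines <- c(lines, sprintf("- %s: %s-%s (%d bands) Rp2=%.3f RMSEP=%.3f RPD=%.3f",
                              b$index, b$band_method, b$family, b$n_bands,
                              b$Rp2, b$RMSEP, b$RPD))
  }
  fails <- attr(grid, "failures")
  if (length(fails)) {
    lines <- c(lines, "", "## Failed cells", "",
               sprintf("- %s: %s", names(fails), unlist(fails)))
  }
  lines
}
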