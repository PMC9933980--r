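# Uniform fit/predict surface over the six regression families. PLS is
# native (see pls.R); SVM, RF and the BP network are backed by e1071,
# randomForest and nnet; the 1-D CNN and LSTM are native (see nn.R).

model_families <- c("PLS", "SVM", "RF", "BP", "CNN", "LSTM")

#' Shipped default parameters for a model family
#'
#' Reads the package's default parameter file (one block per family:
#' PLS components/iterations/tolerance, polynomial-kernel SVM, 200-tree
#' random forest, back-propagation net, Adam-trained CNN and LSTM).
#'
#' @param family one of `"PLS"`, `"SVM"`, `"RF"`, `"BP"`, `"CNN"`,
#'   `"LSTM"`, or `NULL` for the whole list.
#' @return named parameter list.
#' @export
default_model_params <- function(family = NULL) {
  path <- system.file("extdata", "model_defaults.yaml", package = "frostspec")
  defaults <- yaml::read_yaml(path)
  if (is.null(family)) return(defaults)
  family <- toupper(family)
  if (!family %in% names(defaults)) stopf("unknown model family '%s'", family)
  defaults[[family]]
}

#' Specify a regressor
#'
#' @param family model family name.
#' @param params named overrides of the shipped defaults; unknown
#'   parameter names are rejected.
#' @param seed seed for stochastic fits.
#' @return object of class `regressor_spec`.
#' @export
regressor_spec <- function(family, params = list(), seed = 1L) {
  family <- toupper(family)
  if (!family %in% model_families) {
    stopf("unknown model family '%s' (expected one of %s)",
          family, paste(model_families, collapse = ", "))
  }
  defaults <- default_model_params(family)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stopf("unknown parameter(s) for %s: %s", family, paste(unknown, collapse = ", "))
  }
  structure(list(family = family, params = modifyList(defaults, params),
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Fit a regression model to spectra
#'
#' Dispatches on the spec's family and returns a fitted model carrying
#' training metadata (sample count, band count, seed) so that prediction
#' can refuse mismatched band axes.
#'
#' @param spec a [regressor_spec()] (or a family name, taken with
#'   defaults).
#' @param X samples x bands predictor matrix.
#' @param y response vector.
#' @return object of class `frost_model`.
#' @export
fit_regressor <- function(spec, X, y) {
  if (is.character(spec)) spec <- regressor_spec(spec)
  X <- as_matrix(X); y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y))) stopf("fit error: non-finite inputs")
  p <- spec$params
  fit <- tryCatch(switch(spec$family,
    PLS = pls_fit(X, y, ncomp = p$n_components, scale = isTRUE(p$scale),
                  max_iter = p$max_iter, tol = p$tol),
    # a constant target leaves epsilon-SVR with no support vectors (and
    # its internal y-scaling undefined); fall back to the intercept-only
    # linear model in that degenerate case
    SVM = if (sd(y) == 0) pls_fit(X, y, ncomp = 1L) else with_seed(spec$seed,
      e1071::svm(x = X, y = y, kernel = p$kernel, degree = p$degree,
                 cost = p$cost, tolerance = p$tol, cachesize = p$cache_size)),
    RF = with_seed(spec$seed,
      randomForest::randomForest(x = X, y = y, ntree = p$n_estimators,
                                 nodesize = p$min_samples_leaf,
                                 replace = TRUE,
                                 sampsize = ceiling(p$fboot * nrow(X)))),
    BP = with_seed(spec$seed,
      nnet::nnet(x = X, y = y, size = p$hidden_units, linout = TRUE,
                 maxit = p$epochs, abstol = p$goal, decay = 0,
                 MaxNWts = (ncol(X) + 2L) * p$hidden_units + p$hidden_units + 10L,
                 trace = FALSE)),
    CNN = cnn_train(X, y, channels = as.integer(p$channels),
                    pool_size = p$pool_size, dropout = p$dropout,
                    lr = p$learning_rate, epochs = p$epochs,
                    batch_size = p$batch_size, seed = spec$seed),
    LSTM = lstm_train(X, y, hidden_units = p$num_hidden_units,
                      dropout = p$dropout, lr = p$learning_rate,
                      epochs = p$epochs, batch_size = p$batch_size,
                      seed = spec$seed)
  ), error = function(e) stopf("%s fit failed: %s", spec$family, conditionMessage(e)))
  structure(list(family = spec$family, fit = fit, spec = spec,
                 n = nrow(X), n_bands = ncol(X),
                 wavelengths = wavelengths_of(X), seed = spec$seed),
            class = "frost_model")
}

#' Predict from a fitted model
#'
#' @param object a `frost_model`.
#' @param newdata samples x bands matrix with the training band axis.
#' @param ... unused.
#' @return numeric prediction vector, one value per row.
#' @export
predict.frost_model <- function(object, newdata, ...) {
  X <- as_matrix(newdata)
  if (ncol(X) != object$n_bands) {
    stopf("predict error: model was trained on %d bands but input has %d",
          object$n_bands, ncol(X))
  }
  switch(object$family,
    PLS = predict(object$fit, X),
    SVM = as.numeric(predict(object$fit, X)),
    RF = as.numeric(predict(object$fit, X)),
    BP = as.numeric(predict(object$fit, X)),
    CNN = cnn_predict(object$fit, X),
    LSTM = lstm_predict(object$fit, X))
}
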