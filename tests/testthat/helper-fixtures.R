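# Shared fixtures, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small full-design dataset with scored index, memoised per test run.
tea_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 101L)
      rec <- simulate_biochemistry(generate_design(), cfg)
      S <- simulate_spectra(rec, cfg)
      model <- build_ltri(rec[, paste0("X", 1:6)])
      rec <- compute_ltri(rec, model$weights, model$standardizer)
      cache <<- list(records = rec, spectra = S, model = model, config = cfg)
    }
    cache
  }
})

# Spectra with exactly two planted informative bands on a flat baseline:
# the recovery benchmark for the selectors.
planted_band_data <- function(n = 60L, B = 40L, bands = c(10L, 28L),
                              noise = 0.002, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  conc <- matrix(runif(n * length(bands), 0.2, 1), n, length(bands))
  X <- matrix(0.5, n, B)
  for (k in seq_along(bands)) X[, bands[k]] <- X[, bands[k]] - 0.3 * conc[, k]
  X <- X + matrix(rnorm(n * B, sd = noise), n, B)
  coefs <- rep_len(c(1, -0.7, 0.5), length(bands))
  y <- conc %*% coefs + rnorm(n, sd = 0.01)
  list(X = X, y = drop(y), bands = bands)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# matrix subsetting drops custom attributes; reattach the axis
set_wavelengths_for_test <- function(X, wl) {
  attr(X, "wavelengths") <- wl
  X
}
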