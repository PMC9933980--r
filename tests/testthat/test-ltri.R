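ref <- ltri_reference()
lam_ref <- ref$variance$eigenvalue
vc_ref <- ref$variance$vc
cvc2 <- ref$variance$cvc[2]

test_that("standardization yields exact z-scores and round-trips", {
  s <- standardize(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  expect_equal(unname(s$Z[, "a"]), c(-1, 0, 1))
  set.seed(3)
  X <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3)
  s2 <- standardize(X)
  expect_equal(unname(colMeans(s2$Z)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(s2$Z, 2, sd)), rep(1, 3), tolerance = 1e-10)
  back <- sweep(sweep(s2$Z, 2, s2$scale, "*"), 2, s2$center, "+")
  expect_equal(back, X, tolerance = 1e-10)
  expect_error(standardize(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

test_that("correlation PCA has the eigen-structure of the correlation matrix", {
  set.seed(11)
  # p = 2 with known correlation: eigenvalues 1 +/- |r|
  n <- 5000
  x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  Z <- standardize(cbind(x, y))
  p2 <- pca_correlation(Z)
  r <- cor(Z$Z)[1, 2]
  expect_equal(p2$eigenvalues, c(1 + abs(r), 1 - abs(r)), tolerance = 1e-10)
  # independent columns: all eigenvalues near 1, VC near 100/p
  Zi <- standardize(matrix(rnorm(6 * 20000), ncol = 6))
  pi_ <- pca_correlation(Zi)
  expect_true(all(abs(pi_$eigenvalues - 1) < 0.1))
  expect_true(all(abs(pi_$vc - 100 / 6) < 2))
  # invariants on a real panel
  dat <- tea_dataset()
  pc <- pca_correlation(standardize(dat$records[, paste0("X", 1:6)]))
  expect_equal(sum(pc$eigenvalues), 6, tolerance = 1e-10)
  expect_equal(colSums(pc$loadings^2), pc$eigenvalues, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(pc$vc, 100 * pc$eigenvalues / 6, tolerance = 1e-12)
  expect_equal(pc$cvc[6], 100, tolerance = 1e-10)
  # sign convention: largest-|loading| entry of each column positive
  for (j in 1:6) expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
})

test_that("component retention follows the eigenvalue-greater-than-one rule", {
  pca <- list(eigenvalues = lam_ref, cvc = ref$variance$cvc)
  expect_equal(select_components(pca), c(1L, 2L))
  expect_error(select_components(list(eigenvalues = c(0.9, 0.5), cvc = c(64, 100))),
               "no component")
  expect_equal(select_components(pca, "top_k", k = 3), 1:3)
  expect_equal(select_components(pca, "cvc_threshold", threshold = 95), 1:3)
})

test_that("linear combination coefficients divide loadings by sqrt(eigenvalue)", {
  expect_equal(round(0.826 / sqrt(2.862), 3), 0.488)
  expect_equal(round(0.927 / sqrt(2.251), 3), 0.618)
  lcc <- linear_combination_coefficients(ref$loadings, lam_ref[1:2])
  expect_equal(round(lcc["X1", "Y1"], 3), 0.488)
  expect_equal(round(lcc["X2", "Y2"], 3), 0.618)
  expect_equal(linear_combination_coefficients(matrix(sqrt(2.5)), 2.5)[1, 1], 1)
  # unit-norm columns: lcc recovers the unit eigenvector scale
  expect_equal(sum(lcc[, 1]^2), sum(ref$loadings[, 1]^2) / lam_ref[1], tolerance = 1e-12)
  expect_error(linear_combination_coefficients(ref$loadings, c(-1, 2)), "positive")
})

test_that("reported first-component equation holds except its known X4 misprint", {
  lcc <- linear_combination_coefficients(ref$loadings, lam_ref[1:2])
  # five of six printed Y1 entries agree to +/-0.001 ...
  printed_y1 <- c(X1 = 0.488, X2 = -0.063, X3 = 0.377, X5 = -0.484, X6 = 0.521)
  for (v in names(printed_y1)) {
    expect_lt(abs(lcc[v, "Y1"] - printed_y1[[v]]), 1e-3)
  }
  # ... the X4 entry computes to -0.332 (not the printed -0.322), and only
  # -0.332 propagates to the reported composite -0.398
  expect_equal(round(lcc["X4", "Y1"], 3), -0.332)
  csc <- composite_coefficients(lcc, vc_ref[1:2], cvc2)
  expect_equal(round(csc[["X4"]], 3), -0.398)
})

test_that("composite coefficients weight components by variance contribution", {
  lcc <- linear_combination_coefficients(ref$loadings, lam_ref[1:2])
  csc <- composite_coefficients(lcc, vc_ref[1:2], cvc2)
  expect_equal(round(csc[["X3"]], 3), 0.426)
  expect_equal(round(unname(csc), 3), c(0.132, 0.237, 0.426, -0.398, -0.203, 0.228))
  # single retained component collapses to its lcc column
  one <- composite_coefficients(lcc[, 1, drop = FALSE], vc_ref[1], vc_ref[1])
  expect_equal(one, lcc[, 1], tolerance = 1e-12)
  expect_error(composite_coefficients(lcc, c(0, 0), 0), "zero")
})

test_that("percentage normalization preserves signs and sums |w| to one", {
  expect_equal(normalize_coefficients(c(1, -1)), c(0.5, -0.5))
  lcc <- linear_combination_coefficients(ref$loadings, lam_ref[1:2])
  w <- normalize_coefficients(composite_coefficients(lcc, vc_ref[1:2], cvc2))
  expect_equal(round(unname(w), 3), c(0.081, 0.146, 0.262, -0.245, -0.125, 0.141))
  expect_equal(sum(abs(w)), 1, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:5) {
    v <- rnorm(6)
    expect_equal(sum(abs(normalize_coefficients(v))), 1, tolerance = 1e-12)
    expect_equal(sign(normalize_coefficients(v)), sign(v))
  }
  expect_error(normalize_coefficients(rep(0, 6)), "all-zero")
})

test_that("index scoring is a weighted z-score sum with stored standardization", {
  dat <- tea_dataset()
  std <- dat$model$standardizer
  w <- dat$model$weights
  at_means <- as.data.frame(as.list(std$center))
  expect_equal(compute_ltri(at_means, w, std)$ltri, 0, tolerance = 1e-12)
  w1 <- c(1, 0, 0, 0, 0, 0)
  two_sd <- as.data.frame(as.list(std$center + c(2 * std$scale[1], 0, 0, 0, 0, 0)))
  expect_equal(compute_ltri(two_sd, w1, std)$ltri, 2, tolerance = 1e-12)
  bad <- dat$records[1:3, ]; bad$X2[2] <- NA
  expect_error(compute_ltri(bad, w, std), "missing")
  # invariance to affine rescaling of a raw marker when the standardizer is refit
  panel <- dat$records[, paste0("X", 1:6)]
  panel2 <- panel; panel2$X3 <- panel2$X3 * 10 + 100
  m1 <- build_ltri(panel); m2 <- build_ltri(panel2)
  s1 <- compute_ltri(panel, m1$weights, m1$standardizer)$ltri
  s2 <- compute_ltri(panel2, m2$weights, m2$standardizer)$ltri
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("index tracks planted stress severity on synthetic data", {
  # zero noise: treatment means strictly decrease along the severity order
  cfg0 <- generator_config(noise_sd = rep(0, 6))
  rec0 <- simulate_biochemistry(generate_design(), cfg0)
  m0 <- build_ltri(rec0[, paste0("X", 1:6)])
  sc0 <- compute_ltri(rec0, m0$weights, m0$standardizer)
  means0 <- tapply(sc0$ltri, sc0$treatment, mean)[cold_treatments()$label]
  expect_true(all(diff(means0) < 0))
  # default noise: freezing scores clearly below control
  dat <- tea_dataset()
  mn <- tapply(dat$records$ltri, dat$records$treatment, mean)
  expect_lt(mn[["F12"]], mn[["CK8"]])
})

test_that("equation rendering mirrors the reporting format", {
  w <- c(X1 = 0.081, X2 = 0.146, X3 = 0.262, X4 = -0.245, X5 = -0.125, X6 = 0.141)
  expect_equal(ltri_equation(w),
               "LTRI=0.081X1+0.146X2+0.262X3-0.245X4-0.125X5+0.141X6")
})
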