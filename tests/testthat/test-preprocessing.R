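test_that("reflectance correction handles reference identities and reports zeros", {
  R <- matrix(runif(20), 4, 5); D <- matrix(0.1, 4, 5); W <- matrix(0.9, 4, 5)
  expect_equal(reflectance_correction(W, D, W), matrix(1, 4, 5))
  expect_equal(reflectance_correction(D, D, W), matrix(0, 4, 5))
  expect_equal(reflectance_correction(0.6, 0.1, 0.9), 0.625)
  badW <- W; badW[2, 3] <- 0.1
  expect_error(reflectance_correction(R, D, badW), "zero at element")
  # affine invariance: (cR + d, cD + d, cW + d) leaves C unchanged
  C1 <- reflectance_correction(R, D, W)
  C2 <- reflectance_correction(3 * R + 2, 3 * D + 2, 3 * W + 2)
  expect_equal(C1, C2, tolerance = 1e-12)
  # clipping flag
  expect_equal(reflectance_correction(1.2, 0.1, 0.9, clip = TRUE), 1)
})

test_that("ROI extraction isolates known regions", {
  # uniform cube
  vals <- array(0.4, c(4, 4, 6))
  cube <- structure(list(values = vals, wavelengths = 1:6,
                         leaf_mask = matrix(TRUE, 4, 4)), class = "spectral_cube")
  expect_equal(as.numeric(extract_roi_mean(cube, 0.1)$spectrum), rep(0.4, 6))
  # two regions with known spectra: threshold picks the bright one exactly
  spec_hi <- seq(0.5, 0.8, length.out = 6); spec_lo <- rep(0.05, 6)
  vals2 <- array(rep(spec_lo, each = 16), c(4, 4, 6))
  for (b in 1:6) vals2[1:2, , b] <- spec_hi[b]
  cube2 <- structure(list(values = vals2, wavelengths = 1:6), class = "spectral_cube")
  roi <- extract_roi_mean(cube2, threshold = 0.3)
  expect_equal(as.numeric(roi$spectrum), spec_hi)
  expect_equal(sum(roi$mask), 8L)
  # otsu separates bimodal intensities without an explicit threshold
  roi_otsu <- extract_roi_mean(cube2, "otsu")
  expect_equal(as.numeric(roi_otsu$spectrum), spec_hi)
  expect_error(extract_roi_mean(cube2, threshold = 2), "empty ROI")
})

test_that("stacked ROI spectra form the bands-by-samples matrix of the protocol", {
  cfg <- generator_config(pixel_noise_sd = 0.002, seed = 4)
  rec <- simulate_biochemistry(generate_design(), cfg)
  S <- simulate_spectra(rec, cfg)
  cubes <- lapply(seq_len(12), function(i) {
    simulate_cube(S[i, ], c(6L, 6L), background_level = 0.02, cfg, seed = i)
  })
  M <- stack_roi_spectra(cubes)
  expect_equal(dim(t(M)), c(176L, 12L))   # variables x samples orientation
  expect_equal(nrow(generate_design()), 192L)
})

test_that("msc inverts affine scatter exactly", {
  base <- sin(seq(0, 3, length.out = 50)) + 2
  expect_equal(unname(msc(rbind(base), reference = base)[1, ]), base, tolerance = 1e-12)
  expect_equal(unname(msc(rbind(2 * base + 3), reference = base)[1, ]), base,
               tolerance = 1e-10)
  set.seed(9)
  gains <- runif(8, 0.5, 2); offs <- runif(8, -1, 1)
  X <- t(sapply(seq_len(8), function(i) gains[i] * base + offs[i]))
  corrected <- msc(X, reference = base)
  expect_lt(max(abs(sweep(corrected, 2, base))), 1e-10)
  # idempotence
  once <- msc(X)
  expect_equal(msc(once), once, tolerance = 1e-10)
  expect_error(msc(X, reference = rep(1, 50)), "constant")
  expect_error(msc(rbind(base, rep(0, 50) + rnorm(50, sd = 1e-16)), reference = base),
               "degenerate")
})

test_that("savitzky-golay reproduces polynomials and matches a windowed oracle", {
  x <- seq_len(60)
  poly <- 2 + 0.5 * x - 0.01 * x^2
  sm <- savitzky_golay(rbind(poly), window = 11, polyorder = 2)
  expect_equal(unname(sm[1, ]), poly, tolerance = 1e-8)
  # brute-force oracle: independent per-window least squares at interior points
  set.seed(4)
  y <- rnorm(60)
  sm2 <- savitzky_golay(rbind(y), window = 7, polyorder = 3)
  half <- 3L
  for (i in seq.int(half + 1L, 60L - half)) {
    w <- (i - half):(i + half)
    fit <- lm(y[w] ~ poly(seq_along(w), 3, raw = TRUE))
    expect_equal(unname(sm2[1, i]), unname(fitted(fit)[half + 1L]), tolerance = 1e-8)
  }
  # smoothing reduces noise power
  noise <- matrix(rnorm(300), 5, 60)
  smn <- savitzky_golay(noise, window = 11, polyorder = 2)
  expect_lt(var(as.numeric(smn)), var(as.numeric(noise)))
  # polyorder = window - 1 reproduces the input at interior points
  id <- savitzky_golay(rbind(y), window = 5, polyorder = 4)
  expect_equal(id[1, 3:58], y[3:58], tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(savitzky_golay(rbind(y), window = 8), "odd")
  expect_error(savitzky_golay(rbind(y), window = 61), "exceeds")
  expect_error(savitzky_golay(rbind(y), window = 5, polyorder = 5), "polyorder")
})

test_that("first derivative matches hand arithmetic and is linear", {
  expect_equal(unname(first_derivative(rep(0.4, 10), delta_x = 3.5)), rep(0, 9))
  x <- seq(400, 430, by = 3.5)
  expect_equal(unname(first_derivative(0.002 * x, delta_x = 3.5)), rep(0.002, length(x) - 1L))
  d <- first_derivative(c(0.2, 0.5, 0.4), delta_x = 3.5)
  expect_equal(unname(d), c(0.3 / 3.5, -0.1 / 3.5), tolerance = 1e-12)
  expect_equal(unname(d), c(0.0857142857, -0.0285714286), tolerance = 1e-9)
  y <- runif(20); z <- runif(20)
  expect_equal(first_derivative(2 * y + 3 * z, delta_x = 1),
               2 * first_derivative(y, delta_x = 1) + 3 * first_derivative(z, delta_x = 1),
               tolerance = 1e-12)
  expect_error(first_derivative(0.5), "at least 2")
  expect_error(first_derivative(c(1, 2), delta_x = -1), "positive")
})

test_that("preprocess chain composes stages in order and shortens the axis", {
  dat <- tea_dataset()
  S <- dat$spectra[1:20, ]
  S <- set_wavelengths_for_test(S, attr(dat$spectra, "wavelengths"))
  cfg <- preprocess_config()
  out <- preprocess_chain(S, cfg)
  expect_equal(ncol(out), ncol(S) - 1L)
  manual <- first_derivative(savitzky_golay(msc(S), 11, 2))
  expect_equal(as.numeric(out), as.numeric(manual), tolerance = 1e-12)
  expect_equal(attr(out, "preprocessing"), c("msc", "sg(11,2)", "d1"))
  # scatter-distorted replicates collapse after the chain
  base <- dat$spectra[1, ]
  set.seed(2)
  reps <- t(sapply(1:6, function(i) runif(1, 0.8, 1.2) * base + runif(1, -0.05, 0.05)))
  raw_var <- mean(apply(reps, 2, var))
  chained <- preprocess_chain(reps, preprocess_config())
  expect_lt(mean(apply(chained, 2, var)), raw_var)
})
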