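test_that("design generation enumerates the full factorial deterministically", {
  d <- generate_design()
  expect_equal(nrow(d), 192L)
  expect_equal(nrow(generate_design(1L, "ZC108", cold_treatments()[1, ])), 1L)
  expect_equal(nrow(generate_design(3L)), 36L)
  # cultivar-major ordering, treatments in table order
  expect_equal(d$cultivar[1:96], rep("ZC108", 96))
  expect_equal(unique(d$treatment[1:96]), cold_treatments()$label)
  expect_identical(d, generate_design())
  expect_error(generate_design(16L, character(0)), "design error")
  expect_error(generate_design(0L), "design error")
})

test_that("treatment labels map to temperature and duration as designed", {
  tt <- cold_treatments()
  expect_equal(tt$temperature[tt$label == "CK12"], 25)
  expect_equal(tt$duration[tt$label == "F8"], 8)
  expect_equal(tt$temperature[tt$label %in% c("F8", "F12")], c(-4, -4))
})

test_that("biochemistry equals treatment means at zero noise and respects trends", {
  cfg <- generator_config(noise_sd = rep(0, 6))
  rec <- simulate_biochemistry(generate_design(), cfg)
  mu <- cfg$treatment_means
  for (j in 1:6) {
    expect_equal(rec[[paste0("X", j)]], unname(mu[j, rec$treatment]))
  }
  sev <- cold_treatments()$label
  means <- sapply(paste0("X", 1:6), function(v) {
    tapply(rec[[v]], rec$treatment, mean)[sev]
  })
  expect_true(all(diff(means[, "X1"]) < 0))       # SPAD decreasing
  expect_true(all(diff(means[, "X2"]) > 0))       # SS increasing
  expect_true(all(diff(means[, "X3"]) > 0))       # MDA increasing
  for (v in c("X4", "X5", "X6")) {                # enzymes peak under chilling
    peak <- which.max(means[, v])
    expect_true(sev[peak] %in% c("C8", "C12"))
    expect_true(all(diff(means[1:peak, v]) > 0))
    expect_true(all(diff(means[peak:6, v]) < 0))
  }
})

test_that("default-config biochemistry stays within the observed envelopes", {
  rec <- simulate_biochemistry(generate_design(), generator_config(seed = 5))
  env <- rbind(c(39.675, 81.267), c(17, 39.12), c(16, 39.703),
               c(17.159, 38.17), c(1, 12.7), c(242, 438.268))
  inside <- sapply(1:6, function(j) {
    x <- rec[[paste0("X", j)]]
    x >= env[j, 1] & x <= env[j, 2]
  })
  expect_gte(mean(inside), 0.99)
  expect_true(all(as.matrix(rec[paste0("X", 1:6)]) > 0))
})

test_that("large per-cell samples concentrate on configured means", {
  cfg <- generator_config(seed = 2)
  d <- generate_design(2000L, "ZC108", cold_treatments()[3, ])  # C8 cell
  rec <- simulate_biochemistry(d, cfg)
  se <- cfg$noise_sd[["X3"]] / sqrt(nrow(d))
  expect_lt(abs(mean(rec$X3) - cfg$treatment_means["X3", "C8"]), 3 * se)
})

test_that("simulation is seed-reproducible and seed-sensitive", {
  d <- generate_design(2L)
  r1 <- simulate_biochemistry(d, seed = 7)
  r2 <- simulate_biochemistry(d, seed = 7)
  r3 <- simulate_biochemistry(d, seed = 8)
  expect_identical(r1, r2)
  expect_false(identical(r1$X1, r3$X1))
  s1 <- simulate_spectra(r1, seed = 7)
  s2 <- simulate_spectra(r1, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_spectra(r1, seed = 8)))
  expect_error(simulate_biochemistry(transform(d, treatment = "HOT"), generator_config()),
               "config error")
})

test_that("noiseless spectra equal the closed-form mixture", {
  cfg <- generator_config(scatter_gain = c(1, 1), scatter_offset = c(0, 0),
                          band_noise_sd = 0)
  rec <- simulate_biochemistry(generate_design(1L), cfg)
  S <- simulate_spectra(rec, cfg)
  wl <- attr(S, "wavelengths")
  for (i in c(1L, nrow(rec))) {
    expected <- 0.2 + 0.45 / (1 + exp(-(wl - 715) / 20))
    for (k in seq_len(nrow(cfg$signatures))) {
      sig <- cfg$signatures[k, ]
      depth <- sig$amplitude * rec[i, sig$component] / cfg$component_ref[[sig$component]]
      expected <- expected - depth * exp(-((wl - sig$center)^2) / (2 * sig$width^2))
    }
    expect_equal(unname(S[i, ]), expected, tolerance = 1e-12)
  }
})

test_that("spectral axis and chlorophyll linkage match the instrument design", {
  dat <- tea_dataset()
  wl <- attr(dat$spectra, "wavelengths")
  expect_length(wl, 176L)
  expect_equal(range(wl), c(397, 1008))
  expect_equal(mean(diff(wl)), 3.4914, tolerance = 1e-3)
  i_chl <- which.min(abs(wl - 665))
  expect_gt(abs(cor(dat$records$X1, dat$spectra[, i_chl])), 0.5)
})

test_that("informative-band ground truth is non-empty and seed-stable", {
  d <- generate_design(1L)
  r <- simulate_biochemistry(d)
  b1 <- attr(simulate_spectra(r, seed = 1), "informative_bands")
  b2 <- attr(simulate_spectra(r, seed = 99), "informative_bands")
  expect_gt(length(b1), 0L)
  expect_identical(b1, b2)
  expect_error(simulate_spectra(generate_design(1L)), "precondition")
})

test_that("cube ROI recovers the input spectrum", {
  cfg <- generator_config(pixel_noise_sd = 0)
  spec <- seq(0.3, 0.6, length.out = 176)
  cube <- simulate_cube(spec, c(8L, 8L), background_level = 0.02, cfg)
  roi <- extract_roi_mean(cube, threshold = 0.1)
  expect_equal(as.numeric(roi$spectrum), spec, tolerance = 1e-12)
  expect_identical(roi$mask, cube$leaf_mask)

  # all-true mask: ROI equals the full-frame mean
  cube2 <- simulate_cube(spec, c(4L, 4L), background_level = 0.02, cfg,
                         leaf_mask = matrix(TRUE, 4, 4))
  roi2 <- extract_roi_mean(cube2, threshold = 0)
  expect_equal(as.numeric(roi2$spectrum), apply(cube2$values, 3, mean))

  # default pixel noise averages out over the mask
  cfg2 <- generator_config(seed = 3)
  cube3 <- simulate_cube(spec, c(50L, 50L), background_level = 0.02, cfg2)
  roi3 <- extract_roi_mean(cube3, threshold = 0.1)
  se <- cfg2$pixel_noise_sd / sqrt(sum(cube3$leaf_mask))
  expect_true(all(abs(roi3$spectrum - spec) < 4 * se))

  expect_error(simulate_cube(spec, c(8L, 8L), background_level = 0.45),
               "fixture error")
  expect_error(simulate_cube(spec, c(1L, 8L)), "fixture error")
})
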