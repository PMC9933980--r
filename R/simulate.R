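# Synthetic-data generator: experimental design, biochemical responses and
# reflectance spectra/cubes with the statistical structure the downstream
# analysis assumes (planted ground truth for selection/recovery tests).

biochem_vars <- c("X1", "X2", "X3", "X4", "X5", "X6")
biochem_names <- c(X1 = "SPAD", X2 = "SS", X3 = "MDA",
                   X4 = "CAT", X5 = "POD", X6 = "SOD")

#' Cold-treatment design table
#'
#' The six low-temperature treatments: control (25 degC), chilling (4 degC)
#' and freezing (-4 degC), each held for 8 or 12 h. `severity` orders the
#' treatments by stress intensity (CK8 < CK12 < C8 < C12 < F8 < F12).
#'
#' @return data.frame with columns `label`, `temperature` (degC),
#'   `duration` (h) and `severity` (1-6).
#' @export
cold_treatments <- function() {
  data.frame(
    label       = c("CK8", "CK12", "C8", "C12", "F8", "F12"),
    temperature = c(25, 25, 4, 4, -4, -4),
    duration    = c(8, 12, 8, 12, 8, 12),
    severity    = 1:6,
    stringsAsFactors = FALSE
  )
}

#' Generate the sampling design
#'
#' One record per (cultivar, treatment, plant), cultivar-major with
#' treatments in the fixed table order, so the full design of 2 cultivars x
#' 6 treatments x 16 plants yields 192 records in a deterministic order.
#'
#' @param n_plants_per_cell plants sampled per cultivar/treatment cell.
#' @param cultivars character vector of cultivar labels.
#' @param treatments treatment table as from [cold_treatments()].
#' @return data.frame of sample stubs: `sample_id`, `cultivar`,
#'   `treatment`, `plant`.
#' @export
generate_design <- function(n_plants_per_cell = 16L,
                            cultivars = c("ZC108", "LJ43"),
                            treatments = cold_treatments()) {
  if (length(cultivars) < 1L || nrow(treatments) < 1L) {
    stopf("design error: cultivars and treatments must be non-empty")
  }
  if (n_plants_per_cell < 1L) stopf("design error: n_plants_per_cell must be >= 1")
  grid <- expand.grid(plant = seq_len(n_plants_per_cell),
                      treatment = treatments$label,
                      cultivar = cultivars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("cultivar", "treatment", "plant")]
  grid$sample_id <- sprintf("%s_%s_p%02d", grid$cultivar, grid$treatment, grid$plant)
  grid[, c("sample_id", "cultivar", "treatment", "plant")]
}

#' Generator configuration
#'
#' Defaults encode the study conditions the generator emulates: treatment
#' means lie inside the observed min-max envelope of each marker, follow the
#' reported response directions (SPAD falls with stress severity, soluble
#' sugar and MDA rise, the three antioxidant enzymes rise under chilling and
#' fall back under freezing), and noise standard deviations keep +/-3 sd
#' inside the envelope. Spectral signatures tie absorption features to the
#' markers (chlorophyll band near 665 nm for SPAD, 530 nm for MDA-linked
#' pigment change, 960 nm water region for soluble sugar, red edge 715 nm
#' for the enzyme pool); per-sample multiplicative gain/additive offset
#' emulate scatter, plus i.i.d. band noise.
#'
#' @param treatment_means 6 x 6 matrix (markers X1..X6 by treatments
#'   CK8..F12) of noiseless treatment means.
#' @param noise_sd per-marker Gaussian noise sd.
#' @param cultivar_offset additive mean shift applied to the second and
#'   later cultivars (default 0: cultivars pooled).
#' @param signatures data.frame with `component`, `center` (nm), `width`
#'   (nm), `amplitude` (reflectance depth at the marker's reference value).
#' @param component_ref reference marker values scaling signature depth.
#' @param scatter_gain,scatter_offset ranges of the per-sample affine
#'   scatter distortion a*s + b.
#' @param band_noise_sd sd of i.i.d. noise added per band.
#' @param pixel_noise_sd sd of per-pixel noise in simulated cubes.
#' @param wavelengths spectral axis (nm).
#' @param clip_epsilon positivity floor for biochemical values.
#' @param seed integer seed used by the simulation operations.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(treatment_means = NULL,
                             noise_sd = c(2.5, 1.5, 1.5, 1.2, 0.7, 12),
                             cultivar_offset = 0,
                             signatures = NULL,
                             component_ref = c(62.187, 28.524, 27.238, 26.469, 5.973, 359.429),
                             scatter_gain = c(0.95, 1.05),
                             scatter_offset = c(-0.02, 0.02),
                             band_noise_sd = 0.002,
                             pixel_noise_sd = 0.005,
                             wavelengths = default_wavelengths(),
                             clip_epsilon = 1e-6,
                             seed = 1L) {
  if (is.null(treatment_means)) {
    # Means sit >= ~2.5 noise-sd inside the observed min-max envelope of
    # each marker. SPAD falls and SS/MDA rise monotonically with severity;
    # the enzymes rise modestly under chilling and collapse below control
    # levels under freezing (peak at C12), so stress severity remains the
    # dominant covariance axis of the panel.
    treatment_means <- rbind(
      X1 = c(74.5, 72, 66, 62, 54, 46.5),     # SPAD, decreasing
      X2 = c(21.5, 23, 26, 29, 32, 35),       # SS mg/g, increasing
      X3 = c(20, 21.5, 25, 28, 32, 35),       # MDA nmol/g, increasing
      X4 = c(28, 29, 31, 32, 22.5, 20.5),     # CAT, rise then fall
      X5 = c(6, 6.5, 7.5, 8, 3.8, 3),         # POD U/g, rise then fall
      X6 = c(360, 368, 385, 390, 310, 280)    # SOD U/g, rise then fall
    )
    colnames(treatment_means) <- cold_treatments()$label
  }
  if (is.null(signatures)) {
    # every marker is spectrally observable: chlorophyll red absorption for
    # SPAD, water/carbohydrate region for SS, 530 nm pigment-change band
    # for MDA, red-edge feature for CAT, blue carotenoid region for POD,
    # far-NIR band for SOD
    signatures <- data.frame(
      component = c("X1", "X2", "X3", "X4", "X5", "X6"),
      center    = c(665, 960, 530, 715, 445, 985),
      width     = c(40, 45, 30, 25, 25, 20),
      amplitude = c(0.12, 0.08, 0.05, 0.04, 0.03, 0.03),
      stringsAsFactors = FALSE
    )
  }
  if (any(signatures$center < min(wavelengths) | signatures$center > max(wavelengths))) {
    stopf("config error: signature centers must lie within the wavelength axis")
  }
  names(noise_sd) <- names(component_ref) <- biochem_vars
  structure(list(
    treatment_means = treatment_means, noise_sd = noise_sd,
    cultivar_offset = cultivar_offset, signatures = signatures,
    component_ref = component_ref, scatter_gain = scatter_gain,
    scatter_offset = scatter_offset, band_noise_sd = band_noise_sd,
    pixel_noise_sd = pixel_noise_sd, wavelengths = wavelengths,
    clip_epsilon = clip_epsilon, seed = as.integer(seed)
  ), class = "generator_config")
}

#' Simulate biochemical marker values for a design
#'
#' Each marker is its treatment mean plus Gaussian noise, clipped at a small
#' positive floor. With `noise_sd = 0` the values equal the treatment means
#' exactly.
#'
#' @param design data.frame from [generate_design()].
#' @param config [generator_config()].
#' @param seed overrides `config$seed` when given.
#' @return the design with columns `X1`..`X6` appended.
#' @export
simulate_biochemistry <- function(design, config = generator_config(), seed = NULL) {
  seed <- seed %||% config$seed
  mu <- config$treatment_means
  unknown <- setdiff(unique(design$treatment), colnames(mu))
  if (length(unknown)) {
    stopf("config error: unknown treatment label(s): %s", paste(unknown, collapse = ", "))
  }
  cultivar_idx <- match(design$cultivar, unique(design$cultivar)) - 1L
  n <- nrow(design)
  vals <- with_seed(seed, {
    v <- matrix(NA_real_, n, 6, dimnames = list(NULL, biochem_vars))
    for (j in seq_len(6)) {
      m <- mu[j, design$treatment] + config$cultivar_offset * cultivar_idx
      v[, j] <- m + rnorm(n, sd = config$noise_sd[j])
    }
    v
  })
  vals <- pmax(vals, config$clip_epsilon)
  cbind(design, as.data.frame(vals))
}

# Gaussian absorption profile over the wavelength axis.
gaussian_band <- function(wl, center, width) exp(-((wl - center)^2) / (2 * width^2))

# Smooth vegetation-like reflectance baseline: low in the visible, sigmoid
# red edge, high plateau in the NIR.
spectral_baseline <- function(wl) 0.2 + 0.45 / (1 + exp(-(wl - 715) / 20))

# Noiseless mixture spectrum for one sample (no scatter, no noise);
# exported logic of the forward model so tests can recompute it.
pure_spectrum <- function(biochem, config) {
  wl <- config$wavelengths
  s <- spectral_baseline(wl)
  sig <- config$signatures
  for (k in seq_len(nrow(sig))) {
    comp <- sig$component[k]
    depth <- sig$amplitude[k] * biochem[[comp]] / config$component_ref[[comp]]
    s <- s - depth * gaussian_band(wl, sig$center[k], sig$width[k])
  }
  s
}

#' Simulate leaf reflectance spectra
#'
#' Forward model: smooth vegetation baseline minus marker-linked Gaussian
#' absorption features, then a per-sample affine scatter distortion
#' (a * s + b) and i.i.d. band noise. The indices of "informative" bands
#' (within one width of any signature center) are recorded as ground truth
#' in the `informative_bands` attribute.
#'
#' @param records design with biochemistry (from [simulate_biochemistry()]).
#' @param config [generator_config()].
#' @param seed overrides `config$seed`.
#' @return samples x bands matrix of class `spectrum_matrix` with
#'   attributes `wavelengths` and `informative_bands`.
#' @export
simulate_spectra <- function(records, config = generator_config(), seed = NULL) {
  if (!all(biochem_vars %in% names(records))) {
    stopf("precondition error: records lack biochemistry columns X1..X6")
  }
  seed <- seed %||% config$seed
  wl <- config$wavelengths
  n <- nrow(records); B <- length(wl)
  S <- matrix(NA_real_, n, B)
  for (i in seq_len(n)) S[i, ] <- pure_spectrum(records[i, biochem_vars], config)
  S <- with_seed(seed, {
    a <- runif(n, config$scatter_gain[1], config$scatter_gain[2])
    b <- runif(n, config$scatter_offset[1], config$scatter_offset[2])
    S <- S * a + b
    if (config$band_noise_sd > 0) {
      S <- S + matrix(rnorm(n * B, sd = config$band_noise_sd), n, B)
    }
    S
  })
  rownames(S) <- records$sample_id
  S <- set_wavelengths(S, wl)
  sig <- config$signatures
  informative <- sort(unique(unlist(lapply(seq_len(nrow(sig)), function(k) {
    which(abs(wl - sig$center[k]) <= sig$width[k])
  }))))
  attr(S, "informative_bands") <- informative
  class(S) <- c("spectrum_matrix", class(S))
  S
}

#' Simulate a small hyperspectral cube around one spectrum
#'
#' Leaf pixels carry the given spectrum plus pixel noise; background pixels
#' carry a flat low-intensity spectrum. The leaf mask is a centred block
#' covering roughly half the frame (or supplied explicitly).
#'
#' @param spectrum B-vector of leaf reflectance.
#' @param shape c(H, W) frame size, both >= 2.
#' @param background_level flat background reflectance; must stay clearly
#'   below the leaf intensity so threshold segmentation can separate them.
#' @param config [generator_config()] (pixel noise sd, wavelengths).
#' @param leaf_mask optional H x W logical mask; default centred block.
#' @param seed overrides `config$seed`.
#' @return object of class `spectral_cube`: list with `values`
#'   (H x W x B array), `wavelengths`, `leaf_mask`.
#' @export
simulate_cube <- function(spectrum, shape = c(8L, 8L), background_level = 0.02,
                          config = generator_config(), leaf_mask = NULL,
                          seed = NULL) {
  if (any(shape < 2L)) stopf("fixture error: cube shape must be at least 2 x 2")
  H <- shape[1]; W <- shape[2]; B <- length(spectrum)
  leaf_intensity <- mean(spectrum)
  if (background_level >= leaf_intensity - 4 * config$pixel_noise_sd) {
    stopf("fixture error: background level %.3f overlaps leaf intensity %.3f",
          background_level, leaf_intensity)
  }
  if (is.null(leaf_mask)) {
    leaf_mask <- matrix(FALSE, H, W)
    ri <- seq.int(max(1L, floor(H / 4) + 1L), ceiling(3 * H / 4))
    ci <- seq.int(max(1L, floor(W / 4) + 1L), ceiling(3 * W / 4))
    leaf_mask[ri, ci] <- TRUE
  }
  vals <- array(background_level, dim = c(H, W, B))
  idx <- which(leaf_mask)
  for (b in seq_len(B)) {
    plane <- vals[, , b]
    plane[idx] <- spectrum[b]
    vals[, , b] <- plane
  }
  seed <- seed %||% config$seed
  if (config$pixel_noise_sd > 0) {
    vals <- with_seed(seed, vals + array(rnorm(H * W * B, sd = config$pixel_noise_sd),
                                         dim = c(H, W, B)))
  }
  vals <- pmin(pmax(vals, 0), 1)
  wl <- config$wavelengths
  if (length(wl) != B) wl <- default_wavelengths(B)
  structure(list(values = vals, wavelengths = wl, leaf_mask = leaf_mask),
            class = "spectral_cube")
}
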