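# Reflectance correction, ROI mean-spectrum extraction, and the spectral
# pretreatments (MSC, Savitzky-Golay, first derivative).

#' Black/white reflectance correction
#'
#' Converts a raw frame to reflectance as C = (R - D) / (W - D), where D is
#' the dark (lens-cap) reference and W the white-board reference. The
#' correction is invariant to a common affine rescaling of all three frames.
#'
#' @param raw,dark,white conformable numeric arrays (scalar, vector, matrix
#'   or cube); `dark`/`white` may be per-band vectors recycled over pixels
#'   when `raw` is a cube.
#' @param clip clip the result to \[0, 1\] (default off).
#' @return corrected reflectance with the shape of `raw`.
#' @export
reflectance_correction <- function(raw, dark, white, clip = FALSE) {
  denom <- white - dark
  bad <- which(denom == 0)
  if (length(bad)) {
    stopf("reflectance correction error: W - D is zero at element(s) %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  out <- (raw - dark) / denom
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

# Otsu's threshold on a numeric image: maximizes between-class variance on
# a 256-bin histogram of the intensity range.
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((x - r[1]) / diff(r) * nb)), nbins = nb)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nb) - 0.5) / nb * diff(r)
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  mt <- m1[nb]
  between <- (mt * w1 - m1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Extract the ROI mean spectrum from a cube
#'
#' Segments leaf from background by thresholding the mean-over-bands
#' intensity image (Otsu's method by default, or an explicit threshold) and
#' returns the per-band mean over the retained pixels.
#'
#' @param cube a `spectral_cube` (or list with `values` H x W x B and
#'   `wavelengths`).
#' @param threshold `"otsu"` or an explicit numeric intensity threshold;
#'   pixels strictly above it form the ROI.
#' @return list with `spectrum` (B-vector, `wavelengths` attribute),
#'   `mask` (H x W logical) and `threshold` used.
#' @export
extract_roi_mean <- function(cube, threshold = "otsu") {
  vals <- cube$values
  stopifnot(length(dim(vals)) == 3L)
  intensity <- apply(vals, c(1, 2), mean)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(intensity) else as.numeric(threshold)
  mask <- intensity > thr
  if (!any(mask)) stopf("segmentation error: empty ROI at threshold %.4f", thr)
  B <- dim(vals)[3]
  flat <- matrix(vals, ncol = B)
  spectrum <- colMeans(flat[as.vector(mask), , drop = FALSE])
  if (!is.null(cube$wavelengths)) attr(spectrum, "wavelengths") <- cube$wavelengths
  list(spectrum = spectrum, mask = mask, threshold = thr)
}

#' Stack ROI mean spectra from a set of cubes
#'
#' Convenience wrapper producing the bands x samples matrix used downstream
#' (transposed to samples x bands for modeling).
#'
#' @param cubes list of `spectral_cube` objects.
#' @param threshold passed to [extract_roi_mean()].
#' @return samples x bands `spectrum_matrix`.
#' @export
stack_roi_spectra <- function(cubes, threshold = "otsu") {
  rows <- lapply(cubes, function(cb) extract_roi_mean(cb, threshold)$spectrum)
  S <- do.call(rbind, rows)
  wl <- attr(rows[[1]], "wavelengths")
  if (!is.null(wl)) S <- set_wavelengths(S, wl)
  class(S) <- c("spectrum_matrix", class(S))
  S
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, s ~ b * ref + a, and
#' inverts the fitted affine map: corrected = (s - a) / b. Exactly removes
#' per-sample affine (gain/offset) scatter distortions.
#'
#' @param spectra samples x bands matrix.
#' @param reference reference spectrum; default the column mean of
#'   `spectra`. Must be non-constant.
#' @param tol singularity tolerance on the fitted gain `b`.
#' @return corrected matrix with the input's wavelength axis.
#' @export
msc <- function(spectra, reference = NULL, tol = 1e-12) {
  X <- as_matrix(spectra)
  reference <- reference %||% colMeans(X)
  if (sd(reference) == 0) stopf("msc error: reference spectrum is constant")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- X
  for (i in seq_len(nrow(X))) {
    s <- X[i, ]
    b <- sum((s - mean(s)) * rc) / denom
    if (abs(b) < tol) stopf("msc error: degenerate spectrum in row %d (fitted gain ~ 0)", i)
    a <- mean(s) - b * mean(reference)
    out[i, ] <- (s - a) / b
  }
  out <- set_wavelengths(out, wavelengths_of(X))
  attr(out, "informative_bands") <- attr(spectra, "informative_bands")
  out
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the value of the local least-squares polynomial of
#' degree `polyorder` fitted over a centred window; edge points come from
#' the polynomial fits of the terminal windows.
#'
#' @param spectra samples x bands matrix (or a single spectrum).
#' @param window odd window width >= 3, at most the number of bands.
#' @param polyorder polynomial degree, < `window`.
#' @return smoothed matrix of the same shape.
#' @export
savitzky_golay <- function(spectra, window = 11L, polyorder = 2L) {
  X <- as_matrix(spectra)
  B <- ncol(X)
  if (window %% 2L != 1L || window < 3L) stopf("savitzky_golay error: window must be odd and >= 3")
  if (polyorder >= window) stopf("savitzky_golay error: polyorder must be < window")
  if (window > B) stopf("savitzky_golay error: window (%d) exceeds number of bands (%d)", window, B)
  out <- t(apply(X, 1L, signal::sgolayfilt, p = polyorder, n = window))
  dimnames(out) <- dimnames(X)
  out <- set_wavelengths(out, wavelengths_of(X))
  attr(out, "informative_bands") <- attr(spectra, "informative_bands")
  out
}

#' First-difference derivative spectrum
#'
#' out_i = (y_{i+1} - y_i) / delta_x, shortening the band axis by one; the
#' derivative spectrum is placed on midpoint wavelengths.
#'
#' @param spectra samples x bands matrix or a single spectrum (length >= 2).
#' @param delta_x wavelength interval in nm; default the mean spacing of
#'   the attached axis (close to 3.5 nm on the instrument grid).
#' @return matrix (or vector) with one fewer band.
#' @export
first_derivative <- function(spectra, delta_x = NULL) {
  vec_in <- is.null(dim(spectra))
  X <- as_matrix(spectra)
  B <- ncol(X)
  if (B < 2L) stopf("first_derivative error: need at least 2 bands")
  wl <- wavelengths_of(X) %||% attr(spectra, "wavelengths")
  delta_x <- delta_x %||% (if (!is.null(wl)) mean(diff(wl)) else 1)
  if (delta_x <= 0) stopf("first_derivative error: delta_x must be positive")
  out <- (X[, -1L, drop = FALSE] - X[, -B, drop = FALSE]) / delta_x
  rownames(out) <- rownames(X)
  if (!is.null(wl)) out <- set_wavelengths(out, (wl[-1L] + wl[-B]) / 2)
  if (vec_in) {
    v <- drop(out)
    if (!is.null(wl)) attr(v, "wavelengths") <- (wl[-1L] + wl[-B]) / 2
    return(v)
  }
  out
}

#' Preprocessing configuration
#'
#' @param msc,sg,derivative logical switches for the three stages; the
#'   chain applies MSC, then Savitzky-Golay, then the first derivative.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param msc_reference explicit MSC reference spectrum, or `NULL` for the
#'   mean of the processed set.
#' @param derivative_dx explicit wavelength interval for the derivative.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(msc = TRUE, sg = TRUE, derivative = TRUE,
                              sg_window = 11L, sg_polyorder = 2L,
                              msc_reference = NULL, derivative_dx = NULL) {
  structure(list(msc = msc, sg = sg, derivative = derivative,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 msc_reference = msc_reference, derivative_dx = derivative_dx),
            class = "preprocess_config")
}

#' Apply the combined spectral pretreatment chain
#'
#' MSC (scatter removal), then Savitzky-Golay smoothing, then the first
#' derivative, each stage optional via the config. Stage provenance is
#' recorded in the `preprocessing` attribute of the result.
#'
#' @param spectra samples x bands matrix.
#' @param config [preprocess_config()].
#' @return processed matrix (one band shorter when the derivative runs).
#' @export
preprocess_chain <- function(spectra, config = preprocess_config()) {
  out <- as_matrix(spectra)
  out <- set_wavelengths(out, wavelengths_of(spectra))
  attr(out, "informative_bands") <- attr(spectra, "informative_bands")
  stages <- character()
  if (isTRUE(config$msc)) {
    out <- msc(out, reference = config$msc_reference)
    stages <- c(stages, "msc")
  }
  if (isTRUE(config$sg)) {
    out <- savitzky_golay(out, config$sg_window, config$sg_polyorder)
    stages <- c(stages, sprintf("sg(%d,%d)", config$sg_window, config$sg_polyorder))
  }
  if (isTRUE(config$derivative)) {
    out <- first_derivative(out, delta_x = config$derivative_dx)
    stages <- c(stages, "d1")
  }
  attr(out, "preprocessing") <- stages
  out
}
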