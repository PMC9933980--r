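# Plain-text readers/writers for the pipeline's tabular artifacts.

#' Write a spectrum matrix as CSV
#'
#' First column `sample_id`, remaining columns named by wavelength (nm, 3
#' decimals). A companion `<path>.wavelengths.txt` lists the axis.
#'
#' @param spectra samples x bands matrix with wavelength axis.
#' @param path output CSV path.
#' @export
write_spectra <- function(spectra, path) {
  X <- as_matrix(spectra)
  wl <- wavelengths_of(spectra)
  df <- data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)),
                   X, check.names = FALSE)
  colnames(df) <- c("sample_id", sprintf("%.3f", wl %||% seq_len(ncol(X))))
  write.csv(df, path, row.names = FALSE)
  writeLines(sprintf("%.6f", wl %||% seq_len(ncol(X))),
             paste0(path, ".wavelengths.txt"))
  invisible(path)
}

#' Read a spectrum matrix from CSV
#' @param path file written by [write_spectra()].
#' @return samples x bands `spectrum_matrix`.
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df[[1L]]
  wl_file <- paste0(path, ".wavelengths.txt")
  wl <- if (file.exists(wl_file)) as.numeric(readLines(wl_file)) else
    suppressWarnings(as.numeric(colnames(X)))
  X <- set_wavelengths(X, wl)
  class(X) <- c("spectrum_matrix", class(X))
  X
}

#' Write a spectral cube as a multi-page TIFF
#'
#' One 32-bit float page per band; the mask and wavelength axis are written
#' alongside as plain text.
#'
#' @param cube a `spectral_cube`.
#' @param path output TIFF path.
#' @export
write_cube_tiff <- function(cube, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stopf("write_cube_tiff requires the 'tiff' package")
  }
  B <- dim(cube$values)[3]
  pages <- lapply(seq_len(B), function(b) cube$values[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  writeLines(sprintf("%.6f", cube$wavelengths), paste0(path, ".wavelengths.txt"))
  write.csv(cube$leaf_mask * 1L, paste0(path, ".mask.csv"), row.names = FALSE)
  invisible(path)
}
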