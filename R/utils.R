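# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. `seed = NULL` leaves the
# global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a label
# (stage or method name); keeps results independent across stages while
# remaining a pure function of (seed, label). Stays below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% 2147483L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

as_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}

# Wavelength axis attached to a spectrum matrix (columns = bands).
wavelengths_of <- function(x) {
  wl <- attr(x, "wavelengths")
  if (is.null(wl) && !is.null(colnames(x))) {
    wl <- suppressWarnings(as.numeric(colnames(x)))
    if (anyNA(wl)) wl <- NULL
  }
  wl
}

set_wavelengths <- function(x, wl) {
  if (!is.null(wl)) {
    stopifnot(length(wl) == ncol(x))
    attr(x, "wavelengths") <- as.numeric(wl)
    colnames(x) <- sprintf("%.3f", wl)
  }
  x
}

#' Default wavelength axis of the imaging system
#'
#' 176 channels evenly spanning 397-1008 nm (step close to 3.5 nm), the
#' grid on which all shipped defaults and simulations operate.
#'
#' @param n_bands number of spectral channels.
#' @return numeric vector of wavelengths in nm, strictly increasing.
#' @export
default_wavelengths <- function(n_bands = 176L) {
  seq(397, 1008, length.out = n_bands)
}
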