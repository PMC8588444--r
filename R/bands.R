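#' Define a frequency band
#'
#' A band is a half-open interval of frequencies used for FIR band-pass
#' decomposition and for narrowband phase estimation.
#'
#' @param name Band name (e.g. `"Alpha"` or any custom label).
#' @param f_lo,f_hi Lower and upper band edges in Hz; must satisfy
#'   `0 < f_lo < f_hi`.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("Alpha", 8, 13)
#' @export
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || length(f_lo) != 1L ||
      length(f_hi) != 1L || !is.finite(f_lo) || !is.finite(f_hi)) {
    stop("band edges must be finite numbers", call. = FALSE)
  }
  if (!(0 < f_lo && f_lo < f_hi)) {
    stop("invalid band: need 0 < f_lo < f_hi (got [", f_lo, ", ", f_hi, "])",
         call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' The five conventional electrophysiological bands: Delta 1.5-4 Hz, Theta
#' 4-8 Hz, Alpha 8-13 Hz, Beta 13-30 Hz, Gamma 30-80 Hz.
#'
#' @param fs Optional sampling rate in Hz; if given, bands whose upper edge
#'   reaches the Nyquist frequency are rejected with an error.
#' @return A named list of [band_spec()] objects.
#' @examples
#' names(eeg_bands())
#' @export
eeg_bands <- function(fs = NULL) {
  bands <- list(
    Delta = band_spec("Delta", 1.5, 4),
    Theta = band_spec("Theta", 4, 8),
    Alpha = band_spec("Alpha", 8, 13),
    Beta  = band_spec("Beta", 13, 30),
    Gamma = band_spec("Gamma", 30, 80)
  )
  if (!is.null(fs)) {
    for (b in bands) check_band_nyquist(b, fs)
  }
  bands
}

check_band_nyquist <- function(band, fs) {
  stopifnot(inherits(band, "band_spec"))
  if (band$f_hi >= fs / 2) {
    stop("band ", band$name, " [", band$f_lo, ", ", band$f_hi,
         "] Hz exceeds the Nyquist frequency at fs = ", fs, " Hz",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Coerce a list of band_spec (or a single one) to a validated named list.
as_band_list <- function(bands) {
  if (inherits(bands, "band_spec")) bands <- list(bands)
  stopifnot(is.list(bands), length(bands) > 0)
  ok <- vapply(bands, inherits, logical(1), "band_spec")
  if (!all(ok)) stop("`bands` must be band_spec objects", call. = FALSE)
  names(bands) <- vapply(bands, `[[`, character(1), "name")
  bands
}
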