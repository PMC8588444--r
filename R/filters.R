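# Linear-phase FIR least-squares design and strictly zero-phase filtering.
#
# Phase-synchrony estimation cannot tolerate phase distortion, so every
# filter here is a symmetric (type-I) FIR applied forward and backward.
# The design solves the closed-form least-squares normal equations for the
# cosine-series amplitude response over the constrained bands, leaving the
# transition bands unconstrained ("don't care").

# integral of cos(m w) over [a, b]
.cos_int <- function(m, a, b) {
  ifelse(m == 0, b - a, (sin(m * b) - sin(m * a)) / m)
}

# Least-squares type-I FIR for a piecewise-constant desired amplitude.
# bands: data.frame with columns f0, f1 (Hz) and d (desired gain, 0 or 1).
fir_ls_taps <- function(n_taps, fs, bands) {
  if (n_taps %% 2L == 0L) stop("`n_taps` must be odd", call. = FALSE)
  M <- (n_taps - 1L) %/% 2L
  w0 <- 2 * pi * bands$f0 / fs
  w1 <- 2 * pi * bands$f1 / fs
  k <- 0:M
  # normal equations: Q b = r for amplitude A(w) = sum_k b_k cos(k w)
  Q <- matrix(0, M + 1L, M + 1L)
  r <- numeric(M + 1L)
  for (i in seq_along(w0)) {
    S_diff <- outer(k, k, function(a, b) .cos_int(abs(a - b), w0[i], w1[i]))
    S_sum <- outer(k, k, function(a, b) .cos_int(a + b, w0[i], w1[i]))
    Q <- Q + 0.5 * (S_diff + S_sum)
    r <- r + bands$d[i] * .cos_int(k, w0[i], w1[i])
  }
  b <- tryCatch(
    solve(Q, r),
    error = function(e) solve(Q + diag(1e-10 * mean(diag(Q)), M + 1L), r)
  )
  h <- numeric(n_taps)
  h[M + 1L] <- b[1L]
  if (M > 0) {
    h[M + 1L + seq_len(M)] <- b[-1L] / 2
    h[M + 1L - seq_len(M)] <- b[-1L] / 2
  }
  h
}

next_odd <- function(x) {
  n <- ceiling(x)
  if (n %% 2L == 0L) n + 1L else as.integer(n)
}

new_fir_spec <- function(taps, fs, band, transition_width, type) {
  structure(
    list(taps = taps, n_taps = length(taps), fs = fs, band = band,
         transition_width = transition_width, design = "least-squares",
         type = type),
    class = "fir_spec"
  )
}

#' @export
print.fir_spec <- function(x, ...) {
  lab <- if (inherits(x$band, "band_spec")) {
    sprintf("%s %g-%g Hz", x$band$name, x$band$f_lo, x$band$f_hi)
  } else {
    x$type
  }
  cat(sprintf("<fir_spec> %s %s, %d taps @ fs = %g Hz, transition %g Hz\n",
              x$type, lab, x$n_taps, x$fs, x$transition_width))
  invisible(x)
}

#' Design a least-squares linear-phase band-pass FIR filter
#'
#' Solves the closed-form least-squares problem for a symmetric odd-length
#' FIR whose amplitude response approximates 1 inside the band and 0 in the
#' stop bands, with unconstrained transition bands on each side. Symmetric
#' taps guarantee exactly linear phase; applied forward-backward with
#' [filter_zero_phase()] the net phase shift is zero.
#'
#' @param band A [band_spec()].
#' @param fs Sampling rate in Hz.
#' @param transition_width Transition band width in Hz on each side of the
#'   pass band; default 25% of `f_lo`, which keeps the low-frequency Delta
#'   filter realizable at common EEG sampling rates.
#' @param n_taps Odd filter length; default the next odd integer at or above
#'   `max(3 * fs / f_lo, 3.3 * fs / transition_width)` — at least three
#'   cycles of the slowest passband component, and long enough to realize
#'   the requested transition width without material passband ripple.
#' @return A `fir_spec` object with elements `taps`, `n_taps`, `fs`, `band`.
#' @examples
#' fir <- design_fir_ls(band_spec("Alpha", 8, 13), fs = 250)
#' fir$n_taps
#' @export
design_fir_ls <- function(band, fs, transition_width = NULL, n_taps = NULL) {
  stopifnot(inherits(band, "band_spec"))
  check_band_nyquist(band, fs)
  if (is.null(transition_width)) transition_width <- 0.25 * band$f_lo
  if (is.null(n_taps)) {
    n_taps <- next_odd(max(3 * fs / band$f_lo, 3.3 * fs / transition_width))
  }
  if (n_taps %% 2L == 0L) stop("`n_taps` must be odd", call. = FALSE)
  lo <- band$f_lo - transition_width
  hi <- band$f_hi + transition_width
  if (lo <= 0) stop("lower transition band reaches 0 Hz", call. = FALSE)
  if (hi >= fs / 2) stop("upper transition band reaches Nyquist", call. = FALSE)
  taps <- fir_ls_taps(n_taps, fs, data.frame(
    f0 = c(0, band$f_lo, hi),
    f1 = c(lo, band$f_hi, fs / 2),
    d = c(0, 1, 0)
  ))
  new_fir_spec(taps, fs, band, transition_width, "band-pass")
}

# Least-squares low-pass (used for the 80 Hz anti-alias stage).
design_fir_lowpass <- function(cutoff, fs, transition_width = 10,
                               n_taps = NULL) {
  if (cutoff + transition_width >= fs / 2) {
    stop("low-pass transition band reaches Nyquist", call. = FALSE)
  }
  if (is.null(n_taps)) n_taps <- next_odd(3.3 * fs / transition_width)
  taps <- fir_ls_taps(n_taps, fs, data.frame(
    f0 = c(0, cutoff + transition_width),
    f1 = c(cutoff, fs / 2),
    d = c(1, 0)
  ))
  new_fir_spec(taps, fs, band = NULL, transition_width, "low-pass")
}

# Least-squares band-stop (used for the mains notch).
design_fir_bandstop <- function(f_lo, f_hi, fs, transition_width = 2,
                                n_taps = NULL) {
  if (f_lo - transition_width <= 0 || f_hi + transition_width >= fs / 2) {
    stop("band-stop transition bands reach 0 or Nyquist", call. = FALSE)
  }
  if (is.null(n_taps)) n_taps <- next_odd(3.3 * fs / transition_width)
  taps <- fir_ls_taps(n_taps, fs, data.frame(
    f0 = c(0, f_lo, f_hi + transition_width),
    f1 = c(f_lo - transition_width, f_hi, fs / 2),
    d = c(1, 0, 1)
  ))
  new_fir_spec(taps, fs, band = NULL, transition_width, "band-stop")
}

#' Frequency response of a designed FIR filter
#'
#' Evaluates the complex frequency response of the taps at the requested
#' frequencies. With `squared = TRUE` the magnitude of the effective
#' forward-backward (zero-phase) response is returned.
#'
#' @param fspec A `fir_spec` from [design_fir_ls()], or a numeric tap vector
#'   (then `fs` must be supplied).
#' @param f Frequencies in Hz.
#' @param fs Sampling rate, only needed when `fspec` is a bare tap vector.
#' @param squared Return the two-pass magnitude response `|H|^2`?
#' @return Numeric vector of gains (magnitude of the response).
#' @export
fir_gain <- function(fspec, f, fs = NULL, squared = FALSE) {
  if (inherits(fspec, "fir_spec")) {
    taps <- fspec$taps
    fs <- fspec$fs
  } else {
    taps <- fspec
    if (is.null(fs)) stop("`fs` required with bare taps", call. = FALSE)
  }
  w <- 2 * pi * f / fs
  n <- seq_along(taps) - 1
  H <- vapply(w, function(wi) abs(sum(taps * exp(-1i * wi * n))), numeric(1))
  if (squared) H^2 else H
}

# Forward-backward FIR filtering of a single series with odd-reflection
# padding. For symmetric taps this equals convolution with conv(h, h),
# centred, i.e. a strictly zero-phase pass with squared magnitude response.
fir_filtfilt <- function(x, h) {
  n <- length(x)
  N <- length(h)
  if (n <= 3L * N) {
    stop("signal too short for zero-phase filtering (need > 3 x n_taps = ",
         3L * N, " samples, got ", n, ")", call. = FALSE)
  }
  pad <- N
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  g <- fft_conv(h, h)                         # length 2N - 1, symmetric
  yf <- fft_conv(xp, g)
  y <- yf[(N - 1L) + seq_along(xp)]           # remove the group delay of g
  y[(pad + 1L):(pad + n)]
}

# Linear convolution via FFT.
fft_conv <- function(a, b) {
  L <- length(a) + length(b) - 1L
  nfft <- stats::nextn(L, 2)
  Re(fft(fft(c(a, numeric(nfft - length(a)))) *
           fft(c(b, numeric(nfft - length(b)))), inverse = TRUE))[seq_len(L)] / nfft
}

#' Apply a zero-phase FIR filter to a recording
#'
#' Passes every channel forward and backward through the filter, so the
#' effective magnitude response is squared and the net phase response is
#' exactly zero. Odd-reflection padding limits edge transients; `n_taps`
#' samples at each end are nevertheless flagged (via the recording's
#' `edge_margin`) for exclusion from downstream phase statistics.
#'
#' @param rec An [recording()] object with more than `3 * n_taps` samples.
#' @param fspec A `fir_spec` designed at the recording's sampling rate.
#' @return The filtered `eeg_recording` with an updated edge margin.
#' @export
filter_zero_phase <- function(rec, fspec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(fspec, "fir_spec"))
  if (!isTRUE(all.equal(rec$fs, fspec$fs))) {
    stop("filter designed at fs = ", fspec$fs, " but recording has fs = ",
         rec$fs, call. = FALSE)
  }
  out <- t(apply(rec$data, 1L, fir_filtfilt, h = fspec$taps))
  update_data(rec, out, edge_margin = max(rec$edge_margin, fspec$n_taps))
}

#' Remove 50 Hz mains interference
#'
#' Zero-phase FIR band-stop (49-51 Hz by default) applied forward-backward.
#' An FIR notch is used, not an IIR one, so the phase of the retained signal
#' is untouched.
#'
#' @param rec An [recording()] object with `fs > 100`.
#' @param f_lo,f_hi Stop band edges in Hz.
#' @param transition_width Transition width in Hz on each side.
#' @return The notched `eeg_recording`.
#' @export
notch_50 <- function(rec, f_lo = 49, f_hi = 51, transition_width = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 100) {
    stop("50 Hz notch requires fs > 100 Hz (got ", rec$fs, ")", call. = FALSE)
  }
  fspec <- cached_filter(
    paste("notch", f_lo, f_hi, transition_width, rec$fs),
    function() design_fir_bandstop(f_lo, f_hi, rec$fs, transition_width)
  )
  filter_zero_phase(rec, fspec)
}

# Package-level cache so repeated per-subject decompositions reuse designs.
.fir_cache <- new.env(parent = emptyenv())

cached_filter <- function(key, designer) {
  if (is.null(.fir_cache[[key]])) .fir_cache[[key]] <- designer()
  .fir_cache[[key]]
}

#' Decompose a recording into frequency bands
#'
#' Applies the 50 Hz notch and an 80 Hz low-pass, then one zero-phase
#' least-squares band-pass per requested band. Edge margins accumulate and
#' are carried on every output.
#'
#' @param rec An [recording()] object.
#' @param bands A list of [band_spec()] (default [eeg_bands()]).
#' @param lowpass Low-pass cut-off in Hz (`NULL` to skip).
#' @param notch Apply the 50 Hz notch first?
#' @param transition_width,n_taps Passed to [design_fir_ls()] for each band.
#' @return A named list of band-filtered `eeg_recording` objects.
#' @export
band_decompose <- function(rec, bands = eeg_bands(), lowpass = 80,
                           notch = TRUE, transition_width = NULL,
                           n_taps = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  bands <- as_band_list(bands)
  for (b in bands) check_band_nyquist(b, rec$fs)
  if (notch) rec <- notch_50(rec)
  if (!is.null(lowpass)) {
    lp <- cached_filter(
      paste("lowpass", lowpass, rec$fs),
      function() design_fir_lowpass(lowpass, rec$fs)
    )
    rec <- filter_zero_phase(rec, lp)
  }
  lapply(bands, function(b) {
    fspec <- cached_filter(
      paste("band", b$name, b$f_lo, b$f_hi, rec$fs,
            transition_width %||% "def", n_taps %||% "def"),
      function() design_fir_ls(b, rec$fs, transition_width, n_taps)
    )
    filter_zero_phase(rec, fspec)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
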