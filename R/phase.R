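# Analytic signal, instantaneous phase, and phase-synchrony measures.

#' Analytic signal via the Hilbert transform
#'
#' Computes `z = x + i * H(x)` by zeroing the negative-frequency half of the
#' spectrum, so the angle and magnitude of `z` are the instantaneous phase
#' and amplitude of `x`.
#'
#' @param x A finite numeric vector (length >= 8), a channels x samples
#'   matrix, or an [recording()] object.
#' @param ... Unused.
#' @return A complex vector/matrix matching `x` (for a recording, a list
#'   with `z`, `fs`, `edge_margin`).
#' @examples
#' t <- seq(0, 1, by = 1 / 100)
#' z <- analytic_signal(cos(2 * pi * 10 * t))
#' @export
analytic_signal <- function(x, ...) UseMethod("analytic_signal")

#' @export
analytic_signal.numeric <- function(x, ...) {
  n <- length(x)
  if (n < 8L) stop("series too short for the analytic signal", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in input", call. = FALSE)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' @export
analytic_signal.matrix <- function(x, ...) {
  t(apply(x, 1L, analytic_signal.numeric))
}

#' @export
analytic_signal.eeg_recording <- function(x, ...) {
  list(z = analytic_signal.matrix(x$data), fs = x$fs,
       edge_margin = x$edge_margin, channel_labels = x$channel_labels)
}

#' Instantaneous amplitude
#'
#' Magnitude of the analytic signal.
#'
#' @param z Complex analytic series (vector or matrix).
#' @return Non-negative numeric amplitude envelope.
#' @export
instantaneous_amplitude <- function(z) Mod(z)

#' Instantaneous phase
#'
#' Four-quadrant angle of the analytic signal, optionally unwrapped so that
#' consecutive differences lie in `(-pi, pi]` and the phase is continuous.
#' Samples where the analytic amplitude is (numerically) zero have undefined
#' phase; they are set to `NA` with a warning.
#'
#' @param z Complex analytic series (vector or matrix, channels in rows).
#' @param unwrap Remove `2*pi` discontinuities (default `TRUE`)?
#' @param tol Amplitude below which the phase is treated as undefined.
#' @return Numeric phase in radians, same shape as `z`. Wrapped values lie
#'   in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(z, unwrap = TRUE, tol = 1e-12) {
  if (is.matrix(z)) {
    return(t(apply(z, 1L, instantaneous_phase, unwrap = unwrap, tol = tol)))
  }
  scale <- max(Mod(z), tol)
  bad <- Mod(z) < tol * scale
  phi <- Arg(z)
  # Arg returns [-pi, pi]; map -pi to pi for the (-pi, pi] contract
  phi[phi <= -pi] <- pi
  if (any(bad)) {
    warning("phase undefined at ", sum(bad),
            " zero-amplitude sample(s); set to NA")
    phi[bad] <- NA_real_
  }
  if (unwrap) phi <- unwrap_phase(phi)
  phi
}

#' Unwrap a phase series
#'
#' Adds multiples of `2*pi` so that consecutive differences lie in
#' `(-pi, pi]`, producing a continuous phase trajectory.
#'
#' @param phi Numeric phase vector in radians (may contain `NA`).
#' @return Unwrapped phase vector.
#' @export
unwrap_phase <- function(phi) {
  ok <- !is.na(phi)
  p <- phi[ok]
  if (length(p) > 1L) {
    d <- diff(p)
    # map each consecutive difference into (-pi, pi]
    adj <- d - ceiling((d - pi) / (2 * pi)) * 2 * pi
    p <- p[1L] + c(0, cumsum(adj))
  }
  phi[ok] <- p
  phi
}

trim_phases <- function(phi, margin) {
  n <- ncol(phi)
  if (2 * margin >= n) stop("edge margin leaves no interior samples", call. = FALSE)
  phi[, (margin + 1L):(n - margin), drop = FALSE]
}

#' Phase locking value
#'
#' Magnitude of the time-averaged unit phasor of the phase difference
#' between two channels: 1 for perfectly locked phases (including any
#' constant offset), near 0 for unrelated phases.
#'
#' @param phase_x,phase_y Equal-length numeric phase vectors (radians).
#' @return A value in `[0, 1]`.
#' @examples
#' phi <- runif(100, -pi, pi)
#' plv(phi, phi + 1)  # constant offset: still 1
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    stop("phase vectors must have equal length", call. = FALSE)
  }
  if (length(phase_x) < 2L) stop("need at least 2 samples", call. = FALSE)
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Circular mean of a phase sample
#'
#' Angle of the resultant of the unit phasors, computed with the
#' four-quadrant arctangent. When the resultant length is (numerically)
#' zero, e.g. for an antipodal pair, the mean direction is undefined and an
#' error is raised.
#'
#' @param phase Numeric phase vector in radians (length >= 1).
#' @param tol Relative resultant length below which the mean is undefined.
#' @return Mean direction in `(-pi, pi]`.
#' @examples
#' circular_mean(c(0, pi / 2))
#' @export
circular_mean <- function(phase, tol = 1e-8) {
  if (length(phase) < 1L || any(!is.finite(phase))) {
    stop("need a finite, non-empty phase vector", call. = FALSE)
  }
  s <- sum(sin(phase))
  c <- sum(cos(phase))
  if (sqrt(s^2 + c^2) / length(phase) < tol) {
    stop("circular mean undefined: resultant length is zero", call. = FALSE)
  }
  m <- atan2(s, c)
  if (m <= -pi) m <- pi
  m
}

#' Circular correlation of two phase series
#'
#' Circular analogue of Pearson's correlation: the co-variation of the sine
#' deviations of each channel's phase about its circular mean,
#' `sum(sin(x - mx) * sin(y - my)) / sqrt(sum(sin(x - mx)^2) * sum(sin(y - my)^2))`.
#' The raw value lies in `[-1, 1]`; connectivity matrices store its absolute
#' value (and keep the signed value alongside).
#'
#' @param phase_x,phase_y Equal-length numeric phase vectors (radians),
#'   length >= 3, each with non-zero circular variance.
#' @return Raw circular correlation in `[-1, 1]`.
#' @examples
#' phi <- runif(50, -pi, pi)
#' circular_correlation(phi, phi)
#' @export
circular_correlation <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    stop("phase vectors must have equal length", call. = FALSE)
  }
  if (length(phase_x) < 3L) stop("need at least 3 samples", call. = FALSE)
  sx <- sin(phase_x - circular_mean(phase_x))
  sy <- sin(phase_y - circular_mean(phase_y))
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den < 1e-12) {
    stop("circular correlation undefined: a channel has zero circular variance",
         call. = FALSE)
  }
  sum(sx * sy) / den
}

#' Phase-synchrony connectivity matrix
#'
#' Band-filters are assumed already applied; the phase of every channel is
#' extracted from the analytic signal (interior samples only, excluding the
#' filter edge margin) and all unordered channel pairs are scored with the
#' chosen synchrony measure. For `circ_corr` the stored values are absolute
#' circular correlations (range `[0, 1]`); the raw signed matrix is kept in
#' `signed_values`.
#'
#' @param rec A band-filtered [recording()] with at least 2 channels.
#' @param method `"circ_corr"` (default) or `"plv"`.
#' @param band Optional [band_spec()] recorded as metadata.
#' @return An object of class `connectivity_matrix` with fields `values`
#'   (C x C, symmetric, unit diagonal), `signed_values` (for `circ_corr`),
#'   `method`, `band`, `channel_labels`, `n_samples`.
#' @export
connectivity_matrix <- function(rec, method = c("circ_corr", "plv"),
                                band = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "eeg_recording"))
  C <- n_channels(rec)
  if (C < 2L) stop("need at least 2 channels", call. = FALSE)
  idx <- interior_index(rec)
  z <- analytic_signal.matrix(rec$data)[, idx, drop = FALSE]
  phi <- suppressWarnings(instantaneous_phase(z, unwrap = FALSE))
  n <- ncol(phi)
  signed <- NULL
  if (method == "plv") {
    E <- exp(1i * phi)
    vals <- Mod(E %*% Conj(t(E))) / n
  } else {
    sx <- phi
    bad <- logical(C)
    for (i in seq_len(C)) {
      m <- tryCatch(circular_mean(phi[i, ]), error = function(e) NA_real_)
      if (is.na(m)) { bad[i] <- TRUE; next }
      sx[i, ] <- sin(phi[i, ] - m)
    }
    ss <- rowSums(sx^2)
    bad <- bad | ss < 1e-12
    num <- sx %*% t(sx)
    den <- sqrt(outer(ss, ss))
    signed <- num / den
    if (any(bad)) {
      warning("circular correlation undefined for channel(s) ",
              paste(rec$channel_labels[bad], collapse = ", "),
              "; entries set to NA")
      signed[bad, ] <- NA_real_
      signed[, bad] <- NA_real_
    }
    diag(signed) <- 1
    vals <- abs(signed)
    dimnames(signed) <- list(rec$channel_labels, rec$channel_labels)
  }
  diag(vals) <- 1
  vals <- (vals + t(vals)) / 2   # enforce exact symmetry against rounding
  dimnames(vals) <- list(rec$channel_labels, rec$channel_labels)
  structure(
    list(values = vals, signed_values = signed, method = method, band = band,
         channel_labels = rec$channel_labels, n_samples = n,
         subject_id = rec$subject_id, group = rec$group,
         stimulus = rec$stimulus),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d channels, %d samples%s\n",
              x$method, length(x$channel_labels), x$n_samples,
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

#' Flatten a connectivity matrix to its feature vector
#'
#' Fixed row-major upper-triangle ordering (pairs `(1,2), (1,3), ...,
#' (1,C), (2,3), ...`), length `C * (C - 1) / 2`. This ordering is the
#' feature-vector contract used by the SOM and the per-edge tests.
#'
#' @param cm A `connectivity_matrix`, or a bare symmetric matrix.
#' @param signed Use the raw signed circular correlations instead of the
#'   absolute values (only for `circ_corr` matrices)?
#' @return Named numeric vector (`"A-B"` pair names).
#' @export
connectivity_vector <- function(cm, signed = FALSE) {
  m <- if (inherits(cm, "connectivity_matrix")) {
    if (signed) {
      if (is.null(cm$signed_values)) stop("no signed values stored", call. = FALSE)
      cm$signed_values
    } else {
      cm$values
    }
  } else {
    cm
  }
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ut <- upper.tri(m)
  v <- t(m)[t(ut)]                       # row-major upper triangle
  labs <- rownames(m) %||% paste0("ch", seq_len(nrow(m)))
  names(v) <- edge_names(labs)
  v
}

# Row-major upper-triangle pair names for a label vector.
edge_names <- function(labels) {
  C <- length(labels)
  idx <- edge_index(C)
  paste0(labels[idx$i], "-", labels[idx$j])
}

# Row-major upper-triangle index pairs (i < j).
edge_index <- function(C) {
  i <- rep(seq_len(C - 1L), times = (C - 1L):1L)
  j <- unlist(lapply(seq_len(C - 1L), function(k) (k + 1L):C))
  list(i = i, j = j)
}

#' Rebuild a symmetric matrix from a connectivity feature vector
#'
#' Inverse of [connectivity_vector()]: the unit-diagonal symmetric matrix
#' whose row-major upper triangle equals `v`.
#'
#' @param v Numeric vector of length `C * (C - 1) / 2`.
#' @param labels Optional channel labels (length `C`).
#' @return A symmetric `C x C` matrix with unit diagonal.
#' @export
connectivity_from_vector <- function(v, labels = NULL) {
  E <- length(v)
  C <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(C - round(C)) > 1e-9) {
    stop("length ", E, " is not C*(C-1)/2 for any integer C", call. = FALSE)
  }
  C <- as.integer(round(C))
  m <- diag(1, C)
  idx <- edge_index(C)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' @describeIn connectivity_matrix Tidy the edges into a tibble with one row
#'   per unordered channel pair (row-major upper-triangle order).
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  idx <- edge_index(length(x$channel_labels))
  out <- tibble(
    ch_i = x$channel_labels[idx$i],
    ch_j = x$channel_labels[idx$j],
    edge = edge_names(x$channel_labels),
    value = unname(connectivity_vector(x))
  )
  if (!is.null(x$signed_values)) {
    out$signed <- unname(connectivity_vector(x, signed = TRUE))
  }
  out
}

#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$ch_j, y = .data$ch_i, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1), name = object$method) +
    labs(x = NULL, y = NULL,
         title = sprintf("Phase synchrony (%s%s)", object$method,
                         if (!is.null(object$band)) paste0(", ", object$band$name) else "")) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}
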