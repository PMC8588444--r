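# Independent, deliberately naive reference implementations used as oracles.
# These are written as explicit summations so they share no code path with
# the package internals they check.

naive_plv <- function(px, py) {
  n <- length(px)
  s <- 0 + 0i
  for (t in seq_len(n)) s <- s + exp(1i * (px[t] - py[t]))
  Mod(s / n)
}

naive_circular_mean <- function(p) {
  ss <- 0; cc <- 0
  for (t in seq_along(p)) {
    ss <- ss + sin(p[t])
    cc <- cc + cos(p[t])
  }
  atan2(ss, cc)
}

naive_circular_correlation <- function(px, py) {
  mx <- naive_circular_mean(px)
  my <- naive_circular_mean(py)
  num <- 0; dx <- 0; dy <- 0
  for (t in seq_along(px)) {
    sx <- sin(px[t] - mx)
    sy <- sin(py[t] - my)
    num <- num + sx * sy
    dx <- dx + sx^2
    dy <- dy + sy^2
  }
  num / sqrt(dx * dy)
}

# Exhaustive BMU search.
naive_bmu <- function(proto, v) {
  d <- apply(proto, 1L, function(w) sqrt(sum((w - v)^2)))
  c(unit = which.min(d), distance = min(d))
}

# Single-channel sinusoid recording.
sine_recording <- function(f, fs, duration, phase = 0, channels = 1L) {
  t <- seq_len(round(duration * fs)) / fs
  data <- matrix(rep(cos(2 * pi * f * t + phase), channels),
                 nrow = channels, byrow = TRUE)
  recording(data, fs = fs)
}

# Small planted Beta-band cohort spec used in several tests.
planted_beta_spec <- function(n_control, n_case, n_channels, fs = 250,
                              duration = 60, w_control = 0.8, w_case = 0.3,
                              n_edges = n_channels %/% 2, seed = 1,
                              bands = eeg_bands(), noise_sd = 0.5) {
  stopifnot(2 * n_edges <= n_channels)
  edges <- data.frame(band = "Beta",
                      i = seq(1L, by = 2L, length.out = n_edges),
                      j = seq(2L, by = 2L, length.out = n_edges),
                      weight = w_control)
  cohort_spec(n_control, n_case, n_channels = n_channels, fs = fs,
              duration = duration, bands = bands,
              coupling_control = edges,
              coupling_case = transform(edges, weight = w_case),
              noise_sd = noise_sd, seed = seed)
}
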