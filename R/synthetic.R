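# Synthetic two-group EEG cohorts with planted per-band phase coupling.
#
# The generative model is shared-source linear mixing: each channel carries
# an independent narrowband background component per band, and a coupled
# channel pair additionally shares a common narrowband source, so the
# pair's band-phase synchrony grows monotonically with w (weight w on the
# shared source, sqrt(1 - w) on the background). Independent broadband
# Gaussian noise is added on top of the band mixture.

#' Specify a synthetic two-group cohort
#'
#' @param n_control,n_case Subjects per group (both > 0).
#' @param n_channels Channel count (default 31: a 32-electrode montage minus
#'   the reference).
#' @param fs Sampling rate in Hz (default 500); must exceed twice the
#'   highest band edge.
#' @param duration Recording length in seconds (default 60).
#' @param bands Named list of [band_spec()] giving the rhythms present in
#'   the signals (default [eeg_bands()]).
#' @param n_sources Number of independent narrowband background sources
#'   averaged per channel and band (default 1; phase-synchrony ground truth
#'   is insensitive to this).
#' @param coupling_control,coupling_case Coupling tables: data frames with
#'   columns `band` (name matching `bands`), `i`, `j` (distinct 1-based
#'   channel indices) and `weight` in `[0, 1]`.
#' @param noise_sd Standard deviation of the additive broadband noise, in
#'   units of the unit-variance band components (default 0.5; calibrated so
#'   a planted weight of 0.8 yields band circular correlations around
#'   0.5-0.8).
#' @param am_freq Optional amplitude-modulation frequency in Hz applied to
#'   all band sources (emulates amplitude-modulated noise stimuli); default
#'   off.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control, n_case, n_channels = 31L, fs = 500,
                        duration = 60, bands = eeg_bands(), n_sources = 1L,
                        coupling_control = NULL, coupling_case = NULL,
                        noise_sd = 0.5, am_freq = NULL, seed = 1L) {
  stopifnot(n_control > 0, n_case > 0, n_channels >= 2, fs > 0, duration > 0,
            n_sources >= 1)
  bands <- as_band_list(bands)
  fmax <- max(vapply(bands, `[[`, numeric(1), "f_hi"))
  if (fs <= 2 * fmax) {
    stop("fs = ", fs, " must exceed twice the highest band edge (", fmax,
         " Hz)", call. = FALSE)
  }
  validate_coupling <- function(tab, what) {
    if (is.null(tab)) {
      return(tibble(band = character(), i = integer(), j = integer(),
                    weight = numeric()))
    }
    tab <- as_tibble(tab)
    stopifnot(all(c("band", "i", "j", "weight") %in% names(tab)))
    if (!all(tab$band %in% names(bands))) {
      stop("unknown band name in ", what, call. = FALSE)
    }
    if (any(tab$i == tab$j) ||
        any(c(tab$i, tab$j) < 1) || any(c(tab$i, tab$j) > n_channels)) {
      stop(what, ": channel pairs must be distinct valid indices", call. = FALSE)
    }
    if (any(tab$weight < 0 | tab$weight > 1)) {
      stop(what, ": weights must lie in [0, 1]", call. = FALSE)
    }
    # canonical unordered pair ordering i < j
    swap <- tab$i > tab$j
    tmp <- tab$i[swap]; tab$i[swap] <- tab$j[swap]; tab$j[swap] <- tmp
    if (anyDuplicated(tab[, c("band", "i", "j")])) {
      stop(what, ": duplicated (band, pair) entries", call. = FALSE)
    }
    tab
  }
  structure(
    list(n_control = as.integer(n_control), n_case = as.integer(n_case),
         n_channels = as.integer(n_channels), fs = fs, duration = duration,
         bands = bands, n_sources = as.integer(n_sources),
         coupling_control = validate_coupling(coupling_control, "coupling_control"),
         coupling_case = validate_coupling(coupling_case, "coupling_case"),
         noise_sd = noise_sd, am_freq = am_freq, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d control + %d case, %d channels @ %g Hz, %g s, %d band(s)\n",
    x$n_control, x$n_case, x$n_channels, x$fs, x$duration, length(x$bands)))
  cat(sprintf("  planted couplings: %d control / %d case rows, noise_sd = %g, seed = %d\n",
              nrow(x$coupling_control), nrow(x$coupling_case), x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a narrowband source series
#'
#' Band-pass-filtered white Gaussian noise, zero-mean and unit-variance,
#' concentrated in the requested band. Deterministic given the seed.
#'
#' @param band A [band_spec()] within the Nyquist range of `fs`.
#' @param fs Sampling rate in Hz.
#' @param duration Length in seconds.
#' @param seed Integer seed.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
generate_band_source <- function(band, fs, duration, seed) {
  check_band_nyquist(band, fs)
  n <- round(duration * fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  band_source_raw(band, fs, n)
}

# Internal unseeded version: draws from the current RNG stream. Uses a
# tighter transition than the analysis filters so that nearly all source
# power lies strictly inside the nominal band edges.
band_source_raw <- function(band, fs, n) {
  tw <- min(0.25 * band$f_lo, 0.5)
  fspec <- cached_filter(
    paste("src", band$name, band$f_lo, band$f_hi, fs, tw),
    function() design_fir_ls(band, fs, transition_width = tw)
  )
  # generate extra samples so that filter transients can be discarded even
  # for short requested series
  pad <- fspec$n_taps
  x <- rnorm(n + 2L * pad + 3L * fspec$n_taps + 8L)
  y <- fir_filtfilt(x, fspec$taps)
  y <- y[pad + seq_len(n)]
  (y - mean(y)) / sd(y)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Generate one synthetic recording
#'
#' Builds the channel mixture for one subject under the group's coupling
#' table: per band, each channel receives an independent narrowband
#' background, coupled pairs share an extra common source at their planted
#' weight `w` (the background is rescaled to `sqrt(1 - sum(w))`, so the
#' shared fraction of band power grows steeply enough with `w` for phase
#' synchrony to span the weak-to-strong range), and independent broadband
#' Gaussian noise of sd `noise_sd` is added.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Positive integer used for the subject id.
#' @param group `"control"` or `"case"`.
#' @param seed Seed for this subject (defaults to a value derived from the
#'   master seed and the subject index, as in [generate_cohort()]).
#' @return An [recording()] object.
#' @export
generate_recording <- function(spec, subject_index, group, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% c("control", "case")) {
    stop("unknown group label '", group, "'", call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- derive_subject_seeds(spec)[subject_index +
                                         if (group == "case") spec$n_control else 0L]
  }
  coupling <- if (group == "control") spec$coupling_control else spec$coupling_case
  n <- round(spec$duration * spec$fs)
  C <- spec$n_channels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- matrix(rnorm(C * n, sd = spec$noise_sd), nrow = C)
  am <- if (!is.null(spec$am_freq)) {
    tt <- seq_len(n) / spec$fs
    (1 + cos(2 * pi * spec$am_freq * tt)) / 2
  } else {
    NULL
  }
  modulate <- function(s) if (is.null(am)) s else s * am
  for (bname in names(spec$bands)) {
    band <- spec$bands[[bname]]
    rows <- coupling[coupling$band == bname, , drop = FALSE]
    # shared sources, one per planted pair, in table order
    shared <- lapply(seq_len(nrow(rows)), function(k)
      modulate(band_source_raw(band, spec$fs, n)))
    for (ch in seq_len(C)) {
      bg <- if (spec$n_sources == 1L) {
        band_source_raw(band, spec$fs, n)
      } else {
        rowMeans(vapply(seq_len(spec$n_sources), function(s)
          band_source_raw(band, spec$fs, n), numeric(n))) * sqrt(spec$n_sources)
      }
      bg <- modulate(bg)
      k_in <- which(rows$i == ch | rows$j == ch)
      w <- rows$weight[k_in]
      bg_w <- sqrt(max(0, 1 - sum(w)))
      comp <- bg_w * bg
      for (m in seq_along(k_in)) comp <- comp + w[m] * shared[[k_in[m]]]
      x[ch, ] <- x[ch, ] + comp
    }
  }
  recording(x, fs = spec$fs,
            channel_labels = paste0("ch", seq_len(C)),
            subject_id = sprintf("%s_%02d", substr(group, 1, 4), subject_index),
            group = group, stimulus = "none")
}

derive_subject_seeds <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  sample.int(.Machine$integer.max - 1L, spec$n_control + spec$n_case)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces `n_control` control and `n_case` case recordings with
#' independent per-subject seeds derived from the master seed, plus the
#' ground-truth table of planted edges: the (band, pair) entries whose
#' coupling weight differs between the two group tables.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `recordings` (list of [recording()]) and
#'   `ground_truth` (tibble: `band`, `i`, `j`, `weight_control`,
#'   `weight_case`, `effect` = control minus case weight).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_subject_seeds(spec)
  recs <- vector("list", spec$n_control + spec$n_case)
  for (s in seq_len(spec$n_control)) {
    recs[[s]] <- generate_recording(spec, s, "control", seed = seeds[s])
  }
  for (s in seq_len(spec$n_case)) {
    recs[[spec$n_control + s]] <-
      generate_recording(spec, s, "case", seed = seeds[spec$n_control + s])
  }
  list(recordings = recs, ground_truth = cohort_ground_truth(spec))
}

#' Ground-truth planted edges of a cohort specification
#'
#' @param spec A [cohort_spec()].
#' @return Tibble of edges whose weight differs between groups.
#' @export
cohort_ground_truth <- function(spec) {
  a <- spec$coupling_control
  b <- spec$coupling_case
  full <- dplyr::full_join(
    dplyr::rename(a, weight_control = "weight"),
    dplyr::rename(b, weight_case = "weight"),
    by = c("band", "i", "j")
  )
  full$weight_control[is.na(full$weight_control)] <- 0
  full$weight_case[is.na(full$weight_case)] <- 0
  full$effect <- full$weight_control - full$weight_case
  full[full$effect != 0, , drop = FALSE]
}
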