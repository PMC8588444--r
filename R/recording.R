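#' Multichannel EEG recording container
#'
#' A lightweight container for a channels-by-samples signal matrix with its
#' sampling rate and subject metadata. The `edge_margin` attribute tracks how
#' many samples at each end are contaminated by filter edge transients;
#' phase statistics exclude these samples.
#'
#' @param data Numeric matrix, channels x samples; all values finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `data`. Defaults to rownames or `ch1`, `ch2`, ...
#' @param subject_id Subject identifier.
#' @param group One of `"control"`, `"case"`, `"unknown"`.
#' @param stimulus Free-form stimulus tag (e.g. `"4.8Hz"`, `"16Hz"`, `"none"`).
#' @param edge_margin Number of samples at each end to exclude from phase
#'   statistics (non-negative integer).
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(300), 3), fs = 100)
#' rec
#' @export
recording <- function(data, fs, channel_labels = NULL, subject_id = NA_character_,
                      group = c("unknown", "control", "case"),
                      stimulus = "none", edge_margin = 0L) {
  group <- match.arg(group)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("`data` contains non-finite values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("number of channel labels (", length(channel_labels),
         ") does not match number of rows (", nrow(data), ")", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, group = group, stimulus = stimulus,
         edge_margin = as.integer(edge_margin)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, duration(x)))
  cat(sprintf("  subject: %s  group: %s  stimulus: %s  edge margin: %d samples\n",
              x$subject_id, x$group, x$stimulus, x$edge_margin))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [recording()] object.
#' @return Duration in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$data) / rec$fs
}

#' Number of channels
#' @param rec An [recording()] object.
#' @return Integer channel count.
#' @export
n_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nrow(rec$data)
}

# Replace the data matrix, keeping metadata; optionally bump the edge margin.
update_data <- function(rec, data, edge_margin = rec$edge_margin) {
  rec$data <- data
  rownames(rec$data) <- rec$channel_labels
  rec$edge_margin <- as.integer(edge_margin)
  rec
}

# Interior columns once edge transients are excluded.
interior_index <- function(rec) {
  m <- rec$edge_margin
  n <- ncol(rec$data)
  if (2 * m >= n) stop("edge margin leaves no interior samples", call. = FALSE)
  seq.int(m + 1L, n - m)
}

#' Re-reference a recording to one channel
#'
#' Subtracts the reference channel's series from every channel and drops the
#' reference channel from the output (standard monopolar re-referencing, e.g.
#' to Cz).
#'
#' @param rec An [recording()] object.
#' @param ref_label Name of the reference channel; must be present.
#' @return A re-referenced `eeg_recording` with one channel fewer.
#' @export
rereference <- function(rec, ref_label) {
  stopifnot(inherits(rec, "eeg_recording"))
  i <- match(ref_label, rec$channel_labels)
  if (is.na(i)) {
    stop("reference channel '", ref_label, "' not found", call. = FALSE)
  }
  ref <- rec$data[i, ]
  out <- sweep(rec$data[-i, , drop = FALSE], 2L, ref, `-`)
  rec$data <- out
  rec$channel_labels <- rec$channel_labels[-i]
  rownames(rec$data) <- rec$channel_labels
  rec
}

#' Segment a recording into overlapping windows
#'
#' Consecutive analysis windows of `window_s` seconds with `overlap_s`
#' seconds of overlap; a trailing partial window is dropped. Metadata and the
#' edge margin are inherited by every segment.
#'
#' @param rec An [recording()] object.
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (`0 <= overlap_s < window_s`).
#' @return A list of `eeg_recording` segments.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 600), 2), fs = 10)
#' length(segment(rec, 15, 5))
#' @export
segment <- function(rec, window_s, overlap_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(overlap_s >= 0 && overlap_s < window_s)) {
    stop("need 0 <= overlap_s < window_s", call. = FALSE)
  }
  if (window_s > duration(rec)) {
    stop("window (", window_s, " s) longer than recording (",
         duration(rec), " s)", call. = FALSE)
  }
  w <- round(window_s * rec$fs)
  step <- round((window_s - overlap_s) * rec$fs)
  starts <- seq.int(1L, ncol(rec$data) - w + 1L, by = step)
  lapply(starts, function(s) {
    update_data(rec, rec$data[, s:(s + w - 1L), drop = FALSE])
  })
}
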