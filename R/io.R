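# File formats: delimited signal matrices with JSON sidecars, a minimal
# EDF reader/writer (uniform sampling rate, 16-bit), and YAML pipeline
# configuration.

#' Write a recording as a delimited matrix plus JSON sidecar
#'
#' The matrix is tab-separated, channels in rows, with channel labels as
#' row names; the sidecar (`<path>.json`) carries `fs`, `channel_labels`,
#' `subject_id`, `group` and `stimulus`.
#'
#' @param rec An [recording()] object.
#' @param path Output path for the matrix file.
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(
    format(rec$data, digits = 12, scientific = TRUE, trim = TRUE),
    path, sep = "\t", quote = FALSE, col.names = FALSE, row.names = TRUE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         subject_id = rec$subject_id, group = rec$group,
         stimulus = rec$stimulus),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from a delimited matrix plus JSON sidecar
#'
#' @param path Path to the matrix file (channels x samples; first column =
#'   channel labels).
#' @param sidecar Path to the JSON sidecar; defaults to `<path>.json`.
#' @return A validated [recording()] object.
#' @export
read_recording_matrix <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar is missing `fs`: ", sidecar, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  labels <- meta$channel_labels %||% rownames(m)
  if (length(labels) != nrow(m)) {
    stop("sidecar lists ", length(labels), " channels but matrix has ",
         nrow(m), " rows", call. = FALSE)
  }
  recording(unname(m), fs = meta$fs, channel_labels = labels,
            subject_id = meta$subject_id %||% NA_character_,
            group = meta$group %||% "unknown",
            stimulus = meta$stimulus %||% "none")
}

#' Read a recording from an EDF file
#'
#' Minimal European Data Format reader (standard EDF, not EDF+
#' annotations): parses the ASCII header, checks that all selected signals
#' share one sampling rate, and converts the 16-bit samples to physical
#' units with each signal's calibration. Signals sampled at other rates are
#' rejected.
#'
#' @param path Path to an EDF file.
#' @param channels Optional character vector of channel labels to keep
#'   (e.g. to drop a GND channel).
#' @return An [recording()] object.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  version <- hdr_txt(8L)
  if (version != "0") stop("malformed EDF: bad version field", call. = FALSE)
  patient <- hdr_txt(80L)
  recording_id <- hdr_txt(80L)
  hdr_txt(8L); hdr_txt(8L)                     # start date, time
  header_bytes <- as.integer(hdr_txt(8L))
  hdr_txt(44L)                                 # reserved
  n_records <- as.integer(hdr_txt(8L))
  record_dur <- as.numeric(hdr_txt(8L))
  ns <- as.integer(hdr_txt(4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF: bad signal count", call. = FALSE)
  field <- function(nchars) vapply(seq_len(ns), function(i) hdr_txt(nchars),
                                   character(1))
  labels <- field(16L)
  field(80L); field(8L)                        # transducer, dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)                                   # prefiltering
  n_samp <- as.integer(field(8L))
  field(32L)                                   # reserved
  seek(con, header_bytes)
  keep <- if (is.null(channels)) seq_len(ns) else match(channels, labels)
  if (anyNA(keep)) {
    stop("channel(s) not in EDF: ",
         paste(channels[is.na(keep)], collapse = ", "), call. = FALSE)
  }
  if (length(unique(n_samp[keep])) != 1L) {
    stop("unsupported EDF layout: selected channels have mixed sampling rates",
         call. = FALSE)
  }
  fs <- n_samp[keep[1L]] / record_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = length(keep), ncol = n_records * n_samp[keep[1L]])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = n_samp[s], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(raw) < n_samp[s]) stop("malformed EDF: truncated data record",
                                        call. = FALSE)
      k <- match(s, keep)
      if (!is.na(k)) {
        cols <- (r - 1L) * n_samp[s] + seq_len(n_samp[s])
        data[k, cols] <- phys_min[s] + (raw - dig_min[s]) * scale[s]
      }
    }
  }
  recording(data, fs = fs, channel_labels = labels[keep],
            subject_id = if (nzchar(patient)) patient else NA_character_,
            stimulus = if (nzchar(recording_id)) recording_id else "none")
}

#' Write a recording as a minimal EDF file
#'
#' Standard EDF, one data record per second, 16-bit samples scaled to each
#' channel's observed range. Intended for interchange and round-trip
#' testing; requires `fs * 1 s` to be an integer number of samples.
#'
#' @param rec An [recording()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)", call. = FALSE)
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  C <- nrow(data)
  phys_min <- apply(data, 1L, min)
  phys_max <- apply(data, 1L, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768; dig_max <- 32767
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wtxt <- function(x, n) writeBin(charToRaw(pad(x, n)), con)
  wtxt("0", 8L)
  wtxt(ifelse(is.na(rec$subject_id), "X", rec$subject_id), 80L)
  wtxt(rec$stimulus, 80L)
  wtxt("01.01.00", 8L); wtxt("00.00.00", 8L)
  wtxt(256L * (1L + C), 8L)
  wtxt("", 44L)
  wtxt(n_rec, 8L)
  wtxt(1, 8L)
  wtxt(C, 4L)
  for (l in rec$channel_labels) wtxt(l, 16L)
  for (i in seq_len(C)) wtxt("", 80L)
  for (i in seq_len(C)) wtxt("uV", 8L)
  for (i in seq_len(C)) wtxt(formatC(phys_min[i], digits = 6, format = "g"), 8L)
  for (i in seq_len(C)) wtxt(formatC(phys_max[i], digits = 6, format = "g"), 8L)
  for (i in seq_len(C)) wtxt(dig_min, 8L)
  for (i in seq_len(C)) wtxt(dig_max, 8L)
  for (i in seq_len(C)) wtxt("", 80L)
  for (i in seq_len(C)) wtxt(fs, 8L)
  for (i in seq_len(C)) wtxt("", 32L)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * fs + seq_len(fs)
    for (i in seq_len(C)) {
      dig <- round(dig_min + (data[i, cols] - phys_min[i]) * scale[i])
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration for [run_pipeline()]. Every referenced value is
#' validated against the preconditions of the stage that consumes it (band
#' edges against Nyquist, CV fold count, SOM grid, ...) before any
#' computation starts.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    fs = NULL,
    bands = NULL,                 # NULL = the five canonical bands
    reference = NULL,             # channel label to re-reference to
    lowpass = 80, notch = TRUE,
    method = "circ_corr",
    signed = FALSE,
    window_s = NULL, overlap_s = 0,
    som = list(grid = c(8L, 8L), alpha0 = 0.5, sigma0 = NULL,
               n_iter = NULL, seed = 7L),
    cv = list(k = 5L, seed = 1L),
    permutations = 0L,
    fdr_alpha = 0.05, display_p = 0.01
  )
  cfg <- modifyList(defaults, cfg)
  cfg$bands <- if (is.null(cfg$bands)) {
    eeg_bands()
  } else {
    as_band_list(lapply(cfg$bands, function(b) {
      band_spec(b$name, b$f_lo, b$f_hi)
    }))
  }
  if (!cfg$method %in% c("circ_corr", "plv")) {
    stop("config: method must be circ_corr or plv", call. = FALSE)
  }
  if (!is.null(cfg$fs)) {
    for (b in cfg$bands) check_band_nyquist(b, cfg$fs)
  }
  if (cfg$cv$k < 2L) stop("config: cv k must be >= 2", call. = FALSE)
  if (length(cfg$som$grid) != 2L || any(cfg$som$grid < 1L)) {
    stop("config: som grid must be two positive integers", call. = FALSE)
  }
  if (cfg$permutations < 0L) stop("config: permutations must be >= 0", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}
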