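# End-to-end pipeline: preprocessing -> band connectivity -> feature table
# -> per-band cross-validation, permutation test and edge maps.

#' Per-band connectivity features for a set of recordings
#'
#' Runs preprocessing (optional re-referencing, 50 Hz notch, low-pass, band
#' decomposition) and phase-synchrony estimation for every recording, and
#' stacks the upper-triangle connectivity vectors into one feature matrix
#' per band.
#'
#' @param recordings List of [recording()] objects with group metadata.
#' @param bands List of [band_spec()] (default [eeg_bands()]).
#' @param method `"circ_corr"` or `"plv"`.
#' @param reference Optional reference channel label ([rereference()] is
#'   applied when the label is present in a recording).
#' @param lowpass,notch Passed to [band_decompose()].
#' @param signed Use signed circular-correlation features.
#' @param window_s,overlap_s Optional epoching: when `window_s` is set,
#'   connectivity is computed per segment and averaged per subject
#'   (epoch-average mode); default is the full trimmed recording.
#' @return A list with `features` (named list of subject x edge matrices,
#'   one per band), `labels` (group per subject), `subjects`.
#' @export
connectivity_features <- function(recordings, bands = eeg_bands(),
                                  method = c("circ_corr", "plv"),
                                  reference = NULL, lowpass = 80,
                                  notch = TRUE, signed = FALSE,
                                  window_s = NULL, overlap_s = 0) {
  method <- match.arg(method)
  bands <- as_band_list(bands)
  per_subject <- lapply(recordings, function(rec) {
    if (!is.null(reference) && reference %in% rec$channel_labels) {
      rec <- rereference(rec, reference)
    }
    by_band <- band_decompose(rec, bands, lowpass = lowpass, notch = notch)
    lapply(by_band, function(brec) {
      if (is.null(window_s)) {
        connectivity_vector(connectivity_matrix(brec, method), signed = signed)
      } else {
        segs <- segment(brec, window_s, overlap_s)
        vs <- lapply(segs, function(s)
          connectivity_vector(connectivity_matrix(s, method), signed = signed))
        colMeans(do.call(rbind, vs))
      }
    })
  })
  features <- lapply(names(bands), function(b) {
    do.call(rbind, lapply(per_subject, `[[`, b))
  })
  names(features) <- names(bands)
  list(
    features = features,
    labels = vapply(recordings, `[[`, character(1), "group"),
    subjects = vapply(recordings, `[[`, character(1), "subject_id")
  )
}

#' Run the full analysis pipeline
#'
#' Binds the stages together: load (or accept) recordings, extract per-band
#' phase-synchrony features, and per band run stratified cross-validation
#' of the SOM/QE anomaly detector, per-edge Mann-Whitney tests with FDR
#' control, QE band relevance, and (optionally) the label-permutation
#' test. All artifacts can be written to an output directory together with
#' a manifest (configuration, seeds, package version, content hash) for
#' reproducibility.
#'
#' @param config A `pipeline_config` (from [read_pipeline_config()]), a
#'   path to a YAML config, or a list.
#' @param recordings List of [recording()] objects; if `NULL`, all matrix
#'   files in `config$input_dir` are read via [read_recording_matrix()].
#' @param out_dir Optional output directory for delimited result tables and
#'   the JSON manifest.
#' @return A list of class `pipeline_result` with `features`, `cv` (per
#'   band), `edges` (per band), `relevance` (tibble), `permutation` (per
#'   band, if requested), and `manifest`.
#' @export
run_pipeline <- function(config, recordings = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  if (is.null(recordings)) {
    if (is.null(cfg$input_dir)) {
      stop("no recordings given and no input_dir in config", call. = FALSE)
    }
    paths <- list.files(cfg$input_dir, pattern = "\\.tsv$", full.names = TRUE)
    if (length(paths) == 0L) stop("no .tsv recordings in ", cfg$input_dir,
                                  call. = FALSE)
    recordings <- lapply(sort(paths), read_recording_matrix)
  }
  for (rec in recordings) {
    for (b in cfg$bands) check_band_nyquist(b, rec$fs)
  }
  feats <- connectivity_features(
    recordings, bands = cfg$bands, method = cfg$method,
    reference = cfg$reference, lowpass = cfg$lowpass, notch = cfg$notch,
    signed = cfg$signed, window_s = cfg$window_s, overlap_s = cfg$overlap_s)
  labels <- feats$labels
  som <- cfg$som
  results <- list(features = feats, cv = list(), edges = list(),
                  permutation = list())
  relevance <- list()
  for (b in names(feats$features)) {
    x <- feats$features[[b]]
    results$cv[[b]] <- run_cv(
      x, labels, k = cfg$cv$k, seed = cfg$cv$seed, grid = som$grid,
      n_iter = som$n_iter, alpha0 = som$alpha0, sigma0 = som$sigma0, band = b)
    results$edges[[b]] <- edge_tests(
      x[labels == "control", , drop = FALSE],
      x[labels == "case", , drop = FALSE],
      alpha = cfg$fdr_alpha, display = cfg$display_p)
    # whole-cohort QE relevance: map trained on all controls
    model <- fit_som(x[labels == "control", , drop = FALSE], grid = som$grid,
                     n_iter = som$n_iter, alpha0 = som$alpha0,
                     sigma0 = som$sigma0, seed = som$seed)
    qe <- quantization_errors(model, x, meta = tibble(group = labels))
    relevance[[b]] <- tibble(
      band = b,
      kl = band_relevance(qe$qe[qe$group == "control"],
                          qe$qe[qe$group == "case"]),
      mean_qe_control = mean(qe$qe[qe$group == "control"]),
      mean_qe_case = mean(qe$qe[qe$group == "case"]))
    if (cfg$permutations > 0L) {
      results$permutation[[b]] <- permutation_test(
        x, labels, B = cfg$permutations, k = cfg$cv$k, seed = cfg$cv$seed,
        grid = som$grid, n_iter = som$n_iter, alpha0 = som$alpha0,
        sigma0 = som$sigma0)
    }
  }
  results$relevance <- dplyr::bind_rows(relevance)
  summary_tbl <- dplyr::bind_rows(lapply(results$cv, glance))
  results$summary <- summary_tbl
  manifest <- list(
    package_version = as.character(utils::packageVersion("phasesom")),
    config = cfg[setdiff(names(cfg), "bands")],
    bands = lapply(cfg$bands, function(b) list(name = b$name, f_lo = b$f_lo,
                                               f_hi = b$f_hi)),
    n_subjects = length(labels),
    groups = as.list(table(labels)),
    results_hash = rlang::hash(list(summary_tbl, results$relevance))
  )
  manifest$config_hash <- rlang::hash(manifest$config)
  results$manifest <- manifest
  class(results) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(results, out_dir)
  results
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits per-band CV tables, edge-test tables, the band-relevance table, a
#' JSON summary and the manifest. All tables carry header rows; floats are
#' written at 12 significant digits so determinism checks are meaningful.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) signif(col, 12) else col)
    df
  }
  wr <- function(df, name) {
    utils::write.table(fmt(as.data.frame(df)), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cv_all <- dplyr::bind_rows(lapply(names(result$cv), function(b) {
    dplyr::bind_cols(tibble(band = b), tidy(result$cv[[b]]))
  }))
  wr(cv_all, "cv_folds.tsv")
  wr(result$summary, "cv_summary.tsv")
  for (b in names(result$edges)) {
    wr(result$edges[[b]], paste0("edges_", b, ".tsv"))
  }
  wr(result$relevance, "band_relevance.tsv")
  if (length(result$permutation) > 0L) {
    perm <- dplyr::bind_rows(lapply(names(result$permutation), function(b) {
      dplyr::bind_cols(tibble(band = b), glance(result$permutation[[b]]))
    }))
    wr(perm, "permutation.tsv")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    lapply(split(result$summary, result$summary$band), as.list),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' Write a synthetic cohort to disk
#'
#' One delimited matrix + JSON sidecar per subject, plus the ground-truth
#' table as JSON.
#'
#' @param cohort Output of [generate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    write_recording_matrix(rec, file.path(out_dir, paste0(rec$subject_id, ".tsv")))
  }
  jsonlite::write_json(cohort$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Default 32-channel montage labels
#'
#' Extended 10-20 names of a standard 32-electrode actiCAP-style montage
#' (Cz serves as the on-line reference in the acquisition this package
#' targets).
#'
#' @return Character vector of 32 channel labels.
#' @export
montage_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10")
}
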