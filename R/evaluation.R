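# Subject-stratified cross-validation of the QE anomaly detector, ROC/AUC,
# label-permutation significance and per-connection group tests with FDR.

#' Stratified subject-level fold assignment
#'
#' Partitions subjects into `k` folds preserving the class proportions.
#' Folds are assigned at the subject level so that, with epoched data, all
#' epochs of a subject share its fold and no subject leaks between training
#' and test sets.
#'
#' @param labels Character/factor vector of `"control"`/`"case"` per subject.
#' @param k Number of folds (>= 2); every class needs at least `k` subjects.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold assignment (1..k) per subject.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " subjects (smallest has ",
         min(tab), ")", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Binary classification metrics from labels
#'
#' Accuracy, sensitivity (case detection rate) and specificity, with
#' `"case"` as the positive class.
#'
#' @param truth,predicted Character vectors of `"control"`/`"case"`.
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity` and
#'   the confusion counts `tp`, `tn`, `fp`, `fn`.
#' @examples
#' classification_metrics(rep(c("case", "control"), c(2, 2)),
#'                        c("case", "control", "control", "control"))
#' @export
classification_metrics <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  tp <- sum(truth == "case" & predicted == "case")
  tn <- sum(truth == "control" & predicted == "control")
  fp <- sum(truth == "control" & predicted == "case")
  fn <- sum(truth == "case" & predicted == "control")
  tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction:
#' the probability that a random positive (case) scores above a random
#' negative. The curve is the swept-threshold sequence of (FPR, TPR)
#' points, classifying `score > threshold` as case.
#'
#' @param scores Numeric anomaly scores (higher = more case-like).
#' @param labels `"control"`/`"case"` per score; both classes required.
#' @return List with `auc` and `curve` (tibble `threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(2, 4, 1, 3), c("case", "case", "control", "control"))$auc
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "case"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble(
    threshold = th,
    fpr = vapply(th, function(t) sum(scores[!pos] > t) / n0, numeric(1)),
    tpr = vapply(th, function(t) sum(scores[pos] > t) / n1, numeric(1))
  )
  list(auc = unname(auc), curve = curve)
}

# One CV fold of the anomaly pipeline: SOM on control training samples,
# QE + threshold on all training samples, score and classify the test set.
cv_fold <- function(x, labels, train, test, grid, n_iter, alpha0, sigma0,
                    seed, ...) {
  ctrl <- train[labels[train] == "control"]
  if (length(ctrl) < 2L) {
    stop("a fold has fewer than 2 control training subjects", call. = FALSE)
  }
  model <- fit_som(x[ctrl, , drop = FALSE], grid = grid, n_iter = n_iter,
                   alpha0 = alpha0, sigma0 = sigma0, seed = seed, ...)
  qe_train <- quantization_errors(model, x[train, , drop = FALSE])$qe
  thr <- fit_qe_threshold(qe_train, labels[train])
  qe_test <- quantization_errors(model, x[test, , drop = FALSE])$qe
  pred <- classify_qe(thr, qe_test)
  metrics <- classification_metrics(labels[test], pred$label)
  metrics$auc <- roc_auc(qe_test, labels[test])$auc
  list(metrics = metrics, qe_test = qe_test, tau = thr$tau, model = model)
}

#' Cross-validate the SOM quantization-error classifier
#'
#' Stratified subject-level k-fold cross-validation of the full anomaly
#' detector. In each fold a SOM is trained on the control training
#' subjects only, quantization errors are computed for all training
#' subjects, the Bayesian threshold is fitted on them, and the held-out
#' subjects are scored and classified. Metrics are aggregated as mean and
#' across-fold standard deviation.
#'
#' @param x Feature matrix, one row per subject (e.g. stacked
#'   [connectivity_vector()] outputs for one band).
#' @param labels `"control"`/`"case"` per row.
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment, SOM presentation order.
#' @param grid,n_iter,alpha0,sigma0 SOM settings, see [fit_som()].
#' @param band Optional band name stored in the result.
#' @param ... Further arguments to [fit_som()] (e.g. `sigma_min`).
#' @return Object of class `cv_result`: tibble of per-fold metrics plus a
#'   summary; `glance()` gives the mean +/- sd row.
#' @export
run_cv <- function(x, labels, k = 5L, seed = 1L, grid = c(8L, 8L),
                   n_iter = NULL, alpha0 = 0.5, sigma0 = NULL,
                   band = NA_character_, ...) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  fold <- stratified_folds(labels, k, seed)
  folds <- lapply(seq_len(k), function(f) {
    cv_fold(x, labels, train = which(fold != f), test = which(fold == f),
            grid = grid, n_iter = n_iter, alpha0 = alpha0, sigma0 = sigma0,
            seed = seed + f, ...)
  })
  per_fold <- dplyr::bind_rows(lapply(folds, `[[`, "metrics"))
  per_fold <- dplyr::bind_cols(tibble(fold = seq_len(k)), per_fold)
  structure(
    list(folds = per_fold, k = k, seed = seed, band = band,
         mean_accuracy = mean(per_fold$accuracy)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_result> %d-fold%s: accuracy %.3f +/- %.3f, AUC %.3f +/- %.3f\n",
    x$k, if (!is.na(x$band)) paste0(" (", x$band, ")") else "",
    g$accuracy, g$accuracy_sd, g$auc, g$auc_sd))
  invisible(x)
}

#' @describeIn run_cv Per-fold metric tibble.
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @describeIn run_cv Mean and across-fold sd of each metric.
#' @export
glance.cv_result <- function(x, ...) {
  f <- x$folds
  tibble(
    k = x$k, band = x$band,
    accuracy = mean(f$accuracy), accuracy_sd = sd(f$accuracy),
    sensitivity = mean(f$sensitivity), sensitivity_sd = sd(f$sensitivity),
    specificity = mean(f$specificity), specificity_sd = sd(f$specificity),
    auc = mean(f$auc), auc_sd = sd(f$auc)
  )
}

#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$folds[, c("fold", "accuracy", "sensitivity", "specificity", "auc")],
    cols = -"fold", names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    geom_boxplot() +
    geom_point(alpha = 0.6) +
    ylim(0, 1) +
    labs(x = NULL, y = NULL, title = "Cross-validated classification metrics") +
    theme_minimal()
}

#' Label-permutation significance test of the classifier
#'
#' Builds the null distribution of the cross-validated mean accuracy by
#' rerunning the full stratified CV pipeline on `B` random permutations of
#' the subject labels. The empirical p-value is the fraction of null
#' accuracies strictly above the observed one; the smoothed variant
#' `(b + 1) / (B + 1)` is reported alongside, since a plain zero p-value is
#' statistically degenerate.
#'
#' @param x Feature matrix, one row per subject.
#' @param labels `"control"`/`"case"` per row.
#' @param B Number of permutations (>= 1).
#' @param k CV folds.
#' @param seed Master seed (drives folds, SOM and the permutations).
#' @param ... Passed to [run_cv()] (grid, n_iter, ...).
#' @return Object of class `perm_result` with `observed`, `null` (length
#'   B), `p` and `p_smoothed`.
#' @export
permutation_test <- function(x, labels, B = 1000L, k = 5L, seed = 1L, ...) {
  stopifnot(B >= 1L)
  labels <- as.character(labels)
  observed <- run_cv(x, labels, k = k, seed = seed, ...)$mean_accuracy
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perms <- lapply(seq_len(B), function(b) sample(labels))
  perm_seeds <- sample.int(.Machine$integer.max - 1L, B)
  null <- vapply(seq_len(B), function(b) {
    run_cv(x, perms[[b]], k = k, seed = perm_seeds[b], ...)$mean_accuracy
  }, numeric(1))
  b_higher <- sum(null > observed)
  structure(
    list(observed = observed, null = null, B = as.integer(B),
         p = b_higher / B, p_smoothed = (b_higher + 1) / (B + 1)),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "<perm_result> observed accuracy %.3f vs %d permutations: p = %.4g (smoothed %.4g)\n",
    x$observed, x$B, x$p, x$p_smoothed))
  invisible(x)
}

#' @describeIn permutation_test Null accuracies in tibble form.
#' @param x A `perm_result`.
#' @param ... Unused.
#' @export
tidy.perm_result <- function(x, ...) {
  tibble(permutation = seq_len(x$B), accuracy = x$null)
}

#' @describeIn permutation_test One-row summary.
#' @export
glance.perm_result <- function(x, ...) {
  tibble(observed = x$observed, B = x$B, p = x$p, p_smoothed = x$p_smoothed)
}

#' @export
autoplot.perm_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$accuracy)) +
    geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = object$observed, colour = "red") +
    labs(x = "null mean accuracy", y = "count",
         title = sprintf("Permutation test (p = %.3g, smoothed %.3g)",
                         object$p, object$p_smoothed)) +
    theme_minimal()
}

#' Per-connection group comparison with FDR control
#'
#' Two-sided Mann-Whitney test of control vs case connectivity for every
#' edge, with Benjamini-Hochberg adjustment across all edges. The exact
#' null distribution is enumerated when both groups have at most 8 samples;
#' otherwise the normal approximation with tie/continuity correction is
#' used. Edges with adjusted p below `display` carry an extra flag for
#' sparse connection maps.
#'
#' @param x_control,x_case Feature matrices (subjects x edges) in
#'   [connectivity_vector()] order, or lists of `connectivity_matrix`
#'   objects (vectorized automatically). At least 3 subjects per group.
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @param display Adjusted-p threshold for the `display` flag (default 0.01).
#' @return Tibble of class `edge_test_result`: `edge`, `ch_i`, `ch_j`,
#'   `statistic` (Mann-Whitney U for the control group), `p`, `p_adj`,
#'   `significant`, `display`.
#' @export
edge_tests <- function(x_control, x_case, alpha = 0.05, display = 0.01) {
  to_mat <- function(v) {
    if (is.list(v) && !is.data.frame(v) && !is.matrix(v)) {
      do.call(rbind, lapply(v, connectivity_vector))
    } else {
      as.matrix(v)
    }
  }
  xc <- to_mat(x_control); xa <- to_mat(x_case)
  if (nrow(xc) < 3L || nrow(xa) < 3L) {
    stop("need at least 3 subjects per group", call. = FALSE)
  }
  if (ncol(xc) != ncol(xa)) stop("edge sets differ between groups", call. = FALSE)
  exact <- nrow(xc) <= 8L && nrow(xa) <= 8L
  res <- lapply(seq_len(ncol(xc)), function(e) {
    wt <- suppressWarnings(
      wilcox.test(xc[, e], xa[, e], exact = exact, correct = TRUE))
    c(statistic = unname(wt$statistic), p = wt$p.value)
  })
  res <- do.call(rbind, res)
  enames <- colnames(xc) %||% paste0("e", seq_len(ncol(xc)))
  parts <- strsplit(enames, "-", fixed = TRUE)
  out <- tibble(
    edge = enames,
    ch_i = vapply(parts, function(p) p[1], character(1)),
    ch_j = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1)),
    statistic = unname(res[, "statistic"]),
    p = unname(res[, "p"]),
    p_adj = unname(p.adjust(res[, "p"], method = "BH"))
  )
  out$significant <- out$p_adj < alpha
  out$display <- out$p_adj < display
  class(out) <- c("edge_test_result", class(out))
  out
}

#' Plot an edge-test result as a labelled connection map
#'
#' @param edges An `edge_test_result` from [edge_tests()].
#' @param labels Channel labels fixing the axis order (default: order of
#'   appearance).
#' @param flag Which flag column selects shown edges (`"display"` or
#'   `"significant"`).
#' @return A ggplot object.
#' @export
plot_edge_map <- function(edges, labels = NULL, flag = c("display", "significant")) {
  flag <- match.arg(flag)
  if (is.null(labels)) labels <- unique(c(edges$ch_i, edges$ch_j))
  df <- edges[edges[[flag]], , drop = FALSE]
  ggplot(df, aes(x = factor(.data$ch_j, levels = labels),
                 y = factor(.data$ch_i, levels = labels),
                 fill = -log10(.data$p_adj))) +
    geom_tile() +
    scale_x_discrete(drop = FALSE) +
    scale_y_discrete(drop = FALSE) +
    scale_fill_viridis_c(name = "-log10 adj. p") +
    labs(x = NULL, y = NULL,
         title = sprintf("Edges with %s flag (%d of %d)", flag, nrow(df),
                         nrow(edges))) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}
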