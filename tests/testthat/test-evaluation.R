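# Stratified CV, ROC/AUC, permutation significance and per-edge tests.

test_that("stratified folds partition subjects and preserve proportions", {
  labels <- rep(c("control", "case"), c(32, 16))
  fold <- stratified_folds(labels, k = 5, seed = 1)
  expect_length(fold, 48L)
  expect_true(all(fold %in% 1:5))
  for (f in 1:5) {
    expect_true(sum(fold == f & labels == "control") %in% 6:7)
    expect_true(sum(fold == f & labels == "case") %in% 3:4)
  }
  expect_identical(fold, stratified_folds(labels, k = 5, seed = 1))
  expect_false(identical(fold, stratified_folds(labels, k = 5, seed = 2)))
  expect_error(stratified_folds(labels, k = 1), "k must be")
  expect_error(stratified_folds(rep(c("control", "case"), c(20, 3)), k = 5),
               "at least k")
})

test_that("classification metrics reproduce confusion-count arithmetic", {
  truth <- rep(c("case", "control"), c(16, 32))
  pred <- c(rep("case", 15), "control",                 # 15 TP, 1 FN
            rep("control", 30), rep("case", 2))        # 30 TN, 2 FP
  m <- classification_metrics(truth, pred)
  expect_equal(m$accuracy, 45 / 48)
  expect_equal(m$sensitivity, 15 / 16)
  expect_equal(m$specificity, 30 / 32)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(15, 30, 2, 1))
})

test_that("AUC follows the rank formulation with ties and matches pair counting", {
  expect_equal(roc_auc(c(10, 11, 1, 2), rep(c("case", "control"), each = 2))$auc, 1)
  expect_equal(roc_auc(rep(3, 8), rep(c("case", "control"), each = 4))$auc, 0.5)
  # {2, 4} cases vs {1, 3} controls: 3 of 4 concordant pairs
  expect_equal(roc_auc(c(2, 4, 1, 3), c("case", "case", "control", "control"))$auc,
               0.75)
  # brute-force pair counting oracle, with ties counted half
  set.seed(1)
  for (r in 1:10) {
    s <- sample(1:6, 14, replace = TRUE)
    lab <- sample(rep(c("case", "control"), c(6, 8)))
    pos <- s[lab == "case"]; neg <- s[lab == "control"]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(s, lab)$auc, brute, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("case", 3)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(2)
  s <- rnorm(40)
  lab <- sample(rep(c("case", "control"), 20))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = s, levels = c("control", "case"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s, lab)$auc, ref, tolerance = 1e-12)
})

test_that("cross-validation is perfect in the separable limit and leak-free", {
  set.seed(3)
  x <- rbind(matrix(rnorm(15 * 6, 0, 0.2), ncol = 6),
             matrix(rnorm(10 * 6, 8, 0.2), ncol = 6))
  labels <- rep(c("control", "case"), c(15, 10))
  cv <- run_cv(x, labels, k = 5, seed = 4, grid = c(2, 2), n_iter = 500)
  g <- glance(cv)
  expect_equal(g$accuracy, 1)
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity, 1)
  expect_equal(g$auc, 1)
  expect_equal(nrow(tidy(cv)), 5L)

  # every subject is tested exactly once across folds
  fold <- stratified_folds(labels, 5, seed = 4)
  expect_equal(sort(unlist(lapply(1:5, function(f) which(fold == f)))), 1:25)
})

test_that("uninformative features give chance-level CV accuracy", {
  set.seed(5)
  accs <- vapply(1:20, function(s) {
    x <- matrix(rnorm(18 * 8), ncol = 8)
    labels <- rep(c("control", "case"), c(12, 6))
    run_cv(x, labels, k = 3, seed = s, grid = c(2, 2),
           n_iter = 400)$mean_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.75)
})

test_that("permutation test counts exceedances per the empirical-p definition", {
  set.seed(6)
  x <- rbind(matrix(rnorm(12 * 4, 0, 0.2), ncol = 4),
             matrix(rnorm(6 * 4, 6, 0.2), ncol = 4))
  labels <- rep(c("control", "case"), c(12, 6))
  pr <- permutation_test(x, labels, B = 19, k = 3, seed = 7, grid = c(2, 2),
                         n_iter = 300)
  expect_equal(pr$observed, 1)
  expect_equal(pr$p, sum(pr$null > pr$observed) / 19)
  expect_equal(pr$p, 0)                       # nothing beats perfect accuracy
  expect_equal(pr$p_smoothed, 1 / 20)
  expect_length(pr$null, 19L)
  g <- glance(pr)
  expect_equal(g$B, 19L)
})

test_that("a strongly planted band deficit is significant under permutation", {
  spec <- planted_beta_spec(10, 5, n_channels = 8, fs = 250, duration = 20,
                            w_control = 0.9, w_case = 0.1, n_edges = 4,
                            seed = 21, bands = eeg_bands()["Beta"])
  coh <- generate_cohort(spec)
  feats <- connectivity_features(coh$recordings, bands = eeg_bands()["Beta"])
  pr <- permutation_test(feats$features$Beta, feats$labels, B = 19, k = 5,
                         seed = 8, grid = c(2, 2), n_iter = 500)
  expect_lte(pr$p_smoothed, 0.05)
})

test_that("edge tests recover planted differences with exact small-sample p-values", {
  # most extreme 3-vs-3 split: exact two-sided p = 2 / choose(6, 3) = 0.1
  xc <- matrix(c(0.9, 0.8, 0.85), ncol = 1)
  xa <- matrix(c(0.1, 0.2, 0.15), ncol = 1)
  et <- edge_tests(xc, xa)
  expect_equal(et$p, 0.1)
  expect_equal(et$statistic, 9)               # all 9 pairs favour control

  set.seed(9)
  n <- 10; E <- 20
  base <- matrix(rnorm(2 * n * E, 0.5, 0.05), ncol = E)
  shifted <- base
  shifted[(n + 1):(2 * n), 1:5] <- shifted[(n + 1):(2 * n), 1:5] - 0.4
  colnames(base) <- colnames(shifted) <- paste0("c", 1:E, "-c", (1:E) + 1)
  et2 <- edge_tests(base[1:n, ], shifted[(n + 1):(2 * n), ])
  expect_true(all(et2$significant[1:5]))
  expect_true(all(!et2$significant[6:E]))
  expect_true(all(et2$p_adj >= et2$p))
  expect_equal(et2$p_adj, p.adjust(et2$p, "BH"))
  expect_error(edge_tests(base[1:2, ], shifted), "3 subjects")
})

test_that("edge-test power is monotone in effect size and sample size", {
  recovery <- function(delta, n, seed) {
    set.seed(seed)
    E <- 12
    xc <- matrix(rnorm(n * E, 0.5, 0.1), ncol = E)
    xa <- matrix(rnorm(n * E, 0.5, 0.1), ncol = E)
    xa[, 1:4] <- xa[, 1:4] - delta
    mean(edge_tests(xc, xa)$significant[1:4])
  }
  rates <- sapply(c(0.05, 0.12, 0.3), function(d)
    mean(sapply(1:10, function(s) recovery(d, 12, s))))
  expect_true(all(diff(rates) >= 0))
  small <- mean(sapply(1:10, function(s) recovery(0.12, 8, s)))
  large <- mean(sapply(1:10, function(s) recovery(0.12, 24, s)))
  expect_gte(large, small)
})
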