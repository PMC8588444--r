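# SOM initialization, training, BMU/QE scoring, band relevance and the
# Bayesian threshold.

test_that("PCA initialization spans the principal plane deterministically", {
  set.seed(1)
  # data on a 1-D line in 5-D space
  s <- rnorm(40)
  dir <- c(1, -2, 0.5, 3, 1)
  x <- outer(s, dir) + 2
  p <- som_init_pca(x, c(4, 3))
  mu <- colMeans(x)
  for (r in seq_len(nrow(p))) {
    d <- p[r, ] - mu
    resid <- d - dir * sum(d * dir) / sum(dir^2)
    expect_lt(sqrt(sum(resid^2)), 1e-8)
  }
  expect_identical(p, som_init_pca(x, c(4, 3)))
  # 1x1 grid collapses to the data mean
  expect_equal(as.vector(som_init_pca(x, c(1, 1))), mu, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(som_init_pca(x[1, , drop = FALSE], c(2, 2)), "2 samples")
})

test_that("training converges to a repeatedly presented point and improves QE", {
  pt <- c(0.3, -1.2, 2)
  x <- rbind(pt, pt)
  m <- fit_som(x, grid = c(1, 1), n_iter = 500, seed = 2)
  expect_lt(sqrt(sum((m$prototypes[1, ] - pt)^2)), 1e-3)
  expect_lt(quantization_errors(m, x)$qe[1], 1e-3)

  # two well-separated clusters, 2x1 grid: one prototype per centroid
  set.seed(3)
  c1 <- matrix(rnorm(60, 0, 0.1), ncol = 3)
  c2 <- matrix(rnorm(60, 10, 0.1), ncol = 3)
  m2 <- fit_som(rbind(c1, c2), grid = c(2, 1), n_iter = 4000,
                sigma_min = 0.2, seed = 4)
  cents <- rbind(colMeans(c1), colMeans(c2))
  d <- apply(m2$prototypes, 1, function(w)
    min(sqrt(colSums((t(cents) - w)^2))))
  assigned <- apply(m2$prototypes, 1, function(w)
    which.min(sqrt(colSums((t(cents) - w)^2))))
  expect_setequal(assigned, 1:2)
  expect_true(all(d < 0.2))   # well within a cluster radius of each centroid

  # training never worsens the mean training QE vs the PCA initialization
  set.seed(5)
  x3 <- matrix(rnorm(200), ncol = 5)
  m3 <- fit_som(x3, grid = c(3, 3), seed = 6)
  expect_lte(m3$qe_final, m3$qe_init)

  expect_identical(fit_som(x3, grid = c(3, 3), seed = 7)$prototypes,
                   fit_som(x3, grid = c(3, 3), seed = 7)$prototypes)
})

test_that("BMU and QE agree with exhaustive search, ties break low", {
  set.seed(8)
  x <- matrix(rnorm(30 * 4), ncol = 4)
  m <- fit_som(x, grid = c(3, 2), n_iter = 300, seed = 9)
  probes <- matrix(rnorm(50 * 4), ncol = 4)
  b <- som_bmu(m, probes)
  for (r in seq_len(nrow(probes))) {
    ref <- naive_bmu(m$prototypes, probes[r, ])
    expect_equal(b$unit[r], unname(ref["unit"]))
    expect_equal(b$distance[r], unname(ref["distance"]), tolerance = 1e-12)
  }
  # sample equal to a prototype
  b3 <- som_bmu(m, m$prototypes[3, ])
  expect_equal(b3$unit, 3L)
  expect_equal(b3$distance, 0)
  # equidistant tie goes to the lowest linear index
  mt <- m
  mt$prototypes <- rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0))
  mt$grid <- c(2L, 1L); mt$grid_coords <- phasesom:::som_grid_coords(2, 1)
  expect_equal(som_bmu(mt, c(0, 0, 0, 0))$unit, 1L)
  expect_error(som_bmu(m, matrix(0, 1, 7)), "dimension")
})

test_that("receptive fields partition the samples and activation maps flag empty units", {
  set.seed(10)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  m <- fit_som(x, grid = c(2, 2), n_iter = 500, seed = 11)
  q <- quantization_errors(m, x)
  expect_equal(nrow(q), 40L)
  expect_true(all(q$qe >= 0))
  expect_equal(sort(unique(q$sample)), 1:40)   # each sample scored once

  # samples identical to the prototypes quantize with zero error
  q0 <- quantization_errors(m, m$prototypes)
  expect_true(all(q0$qe < 1e-12))
  am0 <- activation_map(m, m$prototypes)
  expect_true(all(am0$mean_qe[am0$n > 0] < 1e-12))

  # a far-away probe set leaves some units empty: flagged NA, not zero
  am <- activation_map(m, matrix(100, 2, 3))
  expect_true(any(am$n == 0))
  expect_true(all(is.na(am$mean_qe[am$n == 0])))
  expect_equal(sum(am$n), 2L)

  # single sample at distance 2 from its unique BMU
  m1 <- m
  m1$prototypes <- matrix(c(0, 0, 0, 50, 50, 50), 2, byrow = TRUE)
  m1$grid <- c(2L, 1L); m1$grid_coords <- phasesom:::som_grid_coords(2, 1)
  q2 <- quantization_errors(m1, matrix(c(2, 0, 0), 1))
  expect_equal(q2$qe, 2)
  expect_error(quantization_errors(m, x[0, , drop = FALSE]), "empty")
})

test_that("symmetrized KL matches hand-derived values and is symmetric", {
  expect_equal(symmetric_kl(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # hand computation: KL(P||Q) = .5 ln(.5/.9) + .5 ln(.5/.1) = 0.5108256,
  # KL(Q||P) = .9 ln(.9/.5) + .1 ln(.1/.5) = 0.3680642, average 0.4394449
  expect_equal(symmetric_kl(c(0.5, 0.5), c(0.9, 0.1)), 0.4394449, tolerance = 1e-6)
  p <- c(0.2, 0.3, 0.5); q <- c(0.6, 0.1, 0.3)
  expect_equal(symmetric_kl(p, q), symmetric_kl(q, p))
  expect_error(symmetric_kl(c(0.5, 0.4), c(0.9, 0.1)), "sum to 1")
})

test_that("band relevance separates shifted QE distributions and rejects degenerate input", {
  set.seed(12)
  a <- rnorm(400, 1, 0.2)
  expect_equal(band_relevance(a, a), 0)
  b_near <- rnorm(400, 1.1, 0.2)
  b_far <- rnorm(400, 2.5, 0.2)
  expect_gt(band_relevance(a, b_far), band_relevance(a, b_near))
  expect_error(band_relevance(numeric(0), a), "non-empty")
  expect_error(band_relevance(rep(1, 10), rep(1, 10)), "degenerate")
})

test_that("threshold sits at the midpoint for the symmetric case and behaves like Bayes", {
  qe <- c(1, 2, 3, 5, 6, 7)
  lab <- rep(c("control", "case"), each = 3)
  m <- fit_qe_threshold(qe, lab)
  expect_equal(m$tau, 4)
  expect_equal(sum(m$priors), 1)
  # posteriors are complementary
  grid <- seq(0, 8, by = 0.1)
  expect_equal(posterior_case(m, grid) +
                 (1 - posterior_case(m, grid)), rep(1, length(grid)))
  # a sample at the control mean is confidently normal
  cl <- classify_qe(m, 2)
  expect_equal(cl$label, "control")
  expect_lt(cl$p_case, 0.5)
  # boundary counts as control; extreme QE is case with posterior -> 1
  expect_equal(classify_qe(m, m$tau)$label, "control")
  far <- classify_qe(m, 50)
  expect_equal(far$label, "case")
  expect_gt(far$p_case, 1 - 1e-6)
  expect_error(classify_qe(m, NaN), "non-finite")
  expect_error(fit_qe_threshold(c(1, 1, 2, 3), rep(c("control", "case"), each = 2)),
               "zero QE variance")
})

test_that("thresholding QE agrees with thresholding the posterior at 1/2", {
  set.seed(13)
  qe <- c(rnorm(200, 1, 0.3), rnorm(200, 2.2, 0.3))
  lab <- rep(c("control", "case"), each = 200)
  m <- fit_qe_threshold(qe, lab)
  probe <- seq(0.2, 3.2, by = 0.01)
  cl <- classify_qe(m, probe)
  # equal-variance-ish case: the two decision rules coincide off the boundary
  agree <- (cl$label == "case") == (cl$p_case > 0.5)
  expect_gt(mean(agree), 0.99)
})

test_that("fitted threshold recovers the analytic posterior crossing", {
  set.seed(14)
  m1 <- 1; s1 <- 0.2; m2 <- 2; s2 <- 0.45
  qe <- c(rnorm(500, m1, s1), rnorm(500, m2, s2))
  lab <- rep(c("control", "case"), each = 500)
  fit <- fit_qe_threshold(qe, lab)
  true_tau <- uniroot(function(x) {
    dnorm(x, m1, s1) - dnorm(x, m2, s2)
  }, c(m1, m2))$root
  expect_lt(abs(fit$tau - true_tau) / true_tau, 0.05)
})
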