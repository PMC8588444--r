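# Self-organizing-map anomaly detection: PCA-initialized lattice, online
# training with exponentially decaying learning rate and Gaussian
# neighbourhood, quantization-error scoring, and map diagnostics.

som_grid_coords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

#' PCA (linear) initialization of SOM prototypes
#'
#' Lays the prototypes out on the plane spanned by the first two principal
#' components of the training data: grid rows span the first component and
#' grid columns the second, each proportionally to the component's standard
#' deviation. Deterministic; a 1 x 1 grid yields the data mean.
#'
#' @param x Numeric matrix of training samples (rows), >= 2 samples.
#' @param grid Integer vector `c(rows, cols)`.
#' @return A `d x p` prototype matrix (`d = rows * cols`), units in
#'   row-major order.
#' @export
som_init_pca <- function(x, grid) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples for PCA initialization",
                         call. = FALSE)
  stopifnot(length(grid) == 2L, all(grid >= 1L))
  rows <- grid[1L]; cols <- grid[2L]
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  mu <- pc$center
  span <- function(k) if (k == 1L) 0 else seq(-1, 1, length.out = k)
  a <- span(rows)            # along PC1
  b <- span(cols)            # along PC2
  d1 <- if (ncol(pc$rotation) >= 1L) pc$sdev[1L] * pc$rotation[, 1L] else numeric(ncol(x))
  d2 <- if (ncol(pc$rotation) >= 2L) pc$sdev[2L] * pc$rotation[, 2L] else numeric(ncol(x))
  coords <- som_grid_coords(rows, cols)
  proto <- matrix(mu, nrow = rows * cols, ncol = ncol(x), byrow = TRUE)
  proto <- proto + outer(a[coords[, "row"]], d1) + outer(b[coords[, "col"]], d2)
  colnames(proto) <- colnames(x)
  proto
}

#' Fit a self-organizing map
#'
#' Online (stochastic) SOM training: at each step one training sample is
#' presented, its best matching unit (BMU) found by Euclidean distance, and
#' every prototype moved toward the sample in proportion to the learning
#' rate and a Gaussian neighbourhood kernel centred on the BMU. Learning
#' rate and neighbourhood width both decay exponentially. Prototypes are
#' PCA-initialized ([som_init_pca()]); the presentation order is drawn from
#' the seed, so training is bit-reproducible.
#'
#' @param x Numeric matrix (samples x features) or data frame, >= 2 rows.
#' @param grid `c(rows, cols)` lattice size; default `c(8, 8)`. A heuristic
#'   alternative is `d ~ 5 * sqrt(N)` total units.
#' @param n_iter Total sample presentations; default `500 * nrow(x)`.
#' @param alpha0 Initial learning rate (default 0.5).
#' @param sigma0 Initial neighbourhood width in grid units (default
#'   `max(grid) / 2`).
#' @param alpha_min,sigma_min Target end-of-schedule values defining the
#'   exponential decay constants. The neighbourhood width decays to half a
#'   lattice spacing, which leaves enough coupling between units for the
#'   map to stay topologically ordered while allowing a fine final
#'   quantization. When the lattice has more units than there are training
#'   samples, prefer a smaller lattice (a common rule of thumb is
#'   `d ~ 5 * sqrt(N)` units) over relying on neighbourhood smoothing, or
#'   the map will reproduce the training samples exactly.
#' @param seed Integer seed driving the presentation order.
#' @return An object of class `som_fit` with `prototypes` (d x p), `grid`,
#'   `grid_coords`, schedule parameters, `seed`, and mean training
#'   quantization error before (`qe_init`) and after (`qe_final`) training.
#' @export
fit_som <- function(x, grid = c(8L, 8L), n_iter = NULL, alpha0 = 0.5,
                    sigma0 = NULL, alpha_min = 0.01, sigma_min = 0.5,
                    seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  N <- nrow(x)
  if (N < 2L) stop("need at least 2 training samples", call. = FALSE)
  stopifnot(length(grid) == 2L, all(grid >= 1L))
  if (is.null(n_iter)) n_iter <- 500L * N
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (is.null(sigma0)) sigma0 <- max(grid) / 2
  proto <- som_init_pca(x, grid)
  coords <- som_grid_coords(grid[1L], grid[2L])
  lambda_alpha <- n_iter / log(alpha0 / alpha_min)
  lambda_sigma <- n_iter / log(max(sigma0 / sigma_min, 1 + 1e-9))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  order <- sample.int(N, n_iter, replace = TRUE)
  qe_init <- mean(som_bmu_cpp(proto, x)$distance)
  trained <- som_train_cpp(proto, x, order - 1L, coords * 1.0,
                           alpha0, sigma0, lambda_alpha, lambda_sigma)
  colnames(trained) <- colnames(x)
  structure(
    list(prototypes = trained, grid = as.integer(grid), grid_coords = coords,
         n_iter = as.integer(n_iter), alpha0 = alpha0, sigma0 = sigma0,
         alpha_min = alpha_min, sigma_min = sigma_min, seed = as.integer(seed),
         qe_init = qe_init,
         qe_final = mean(som_bmu_cpp(trained, x)$distance),
         n_train = N),
    class = "som_fit"
  )
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("<som_fit> %d x %d lattice, %d features, %d presentations\n",
              x$grid[1], x$grid[2], ncol(x$prototypes), x$n_iter))
  cat(sprintf("  mean training QE: %.4g (init) -> %.4g (trained)\n",
              x$qe_init, x$qe_final))
  invisible(x)
}

check_som_dim <- function(model, x) {
  if (ncol(x) != ncol(model$prototypes)) {
    stop("feature dimension (", ncol(x), ") does not match the map (",
         ncol(model$prototypes), ")", call. = FALSE)
  }
}

#' Best matching unit
#'
#' The prototype nearest each sample in Euclidean distance; ties are broken
#' by the lowest linear unit index.
#'
#' @param model A `som_fit`.
#' @param x Sample matrix (rows) or a single numeric vector.
#' @return Tibble with `unit` (1-based linear index) and `distance`.
#' @export
som_bmu <- function(model, x) {
  stopifnot(inherits(model, "som_fit"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  check_som_dim(model, x)
  r <- som_bmu_cpp(model$prototypes, x)
  tibble(unit = r$unit, distance = r$distance)
}

#' Quantization errors of a sample set
#'
#' Distance of every sample to its BMU: the anomaly score of the method.
#' Metadata columns (subject, group, band, ...) can be attached for
#' downstream threshold fitting and band-relevance analysis.
#'
#' @param model A `som_fit`.
#' @param x Sample matrix (non-empty).
#' @param meta Optional data frame with one row per sample to bind on.
#' @return Tibble with `sample`, `unit`, `qe`, plus any `meta` columns.
#' @export
quantization_errors <- function(model, x, meta = NULL) {
  stopifnot(inherits(model, "som_fit"))
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty sample set", call. = FALSE)
  b <- som_bmu(model, x)
  out <- tibble(sample = seq_len(nrow(x)), unit = b$unit, qe = b$distance)
  if (!is.null(meta)) {
    stopifnot(nrow(meta) == nrow(x))
    out <- dplyr::bind_cols(out, as_tibble(meta))
  }
  out
}

#' Per-unit activation map
#'
#' Mean quantization error of each unit over its receptive field (the
#' samples for which it is the BMU). Units with empty receptive fields get
#' `NA` (flagged, not zero). On a planted cohort, case maps show higher mean
#' QE than control maps.
#'
#' @param model A `som_fit`.
#' @param x Sample matrix.
#' @return Tibble with `unit`, `row`, `col`, `n` (receptive-field size) and
#'   `mean_qe`, of class `som_activation`.
#' @export
activation_map <- function(model, x) {
  q <- quantization_errors(model, x)
  d <- nrow(model$prototypes)
  agg <- dplyr::summarise(dplyr::group_by(q, .data$unit),
                          n = dplyr::n(), mean_qe = mean(.data$qe))
  out <- tibble(unit = seq_len(d),
                row = model$grid_coords[, "row"],
                col = model$grid_coords[, "col"]) |>
    left_join(agg, by = "unit") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  class(out) <- c("som_activation", class(out))
  out
}

#' @export
autoplot.som_activation <- function(object, ...) {
  ggplot(object, aes(x = .data$col, y = .data$row, fill = .data$mean_qe)) +
    geom_tile(colour = "grey80") +
    scale_fill_viridis_c(name = "mean QE", na.value = "white") +
    scale_y_reverse() +
    coord_equal() +
    labs(x = NULL, y = NULL, title = "SOM activation (mean quantization error)") +
    theme_minimal()
}

#' @describeIn fit_som Prototype vectors in long tibble form.
#' @param x A `som_fit`.
#' @param ... Unused.
#' @export
tidy.som_fit <- function(x, ...) {
  p <- x$prototypes
  feat <- colnames(p) %||% paste0("f", seq_len(ncol(p)))
  tibble(
    unit = rep(seq_len(nrow(p)), times = ncol(p)),
    row = rep(x$grid_coords[, "row"], times = ncol(p)),
    col = rep(x$grid_coords[, "col"], times = ncol(p)),
    feature = rep(feat, each = nrow(p)),
    value = as.vector(p)
  )
}

#' @describeIn fit_som One-row training summary.
#' @export
glance.som_fit <- function(x, ...) {
  tibble(n_units = nrow(x$prototypes), n_features = ncol(x$prototypes),
         n_train = x$n_train, n_iter = x$n_iter, alpha0 = x$alpha0,
         sigma0 = x$sigma0, seed = x$seed,
         qe_init = x$qe_init, qe_final = x$qe_final)
}

#' Symmetrized Kullback-Leibler divergence of two discrete distributions
#'
#' `0.5 * (KL(P||Q) + KL(Q||P))` in nats, with `KL(P||Q) = sum(P *
#' log(P/Q))` and the convention `0 * log(0) = 0`.
#'
#' @param p,q Probability vectors of equal length (each summing to 1).
#' @return Symmetrized divergence in nats (non-negative; `Inf` if one
#'   distribution has mass where the other has none).
#' @examples
#' symmetric_kl(c(0.5, 0.5), c(0.9, 0.1))
#' @export
symmetric_kl <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("`p` and `q` must each sum to 1", call. = FALSE)
  }
  kl <- function(a, b) {
    i <- a > 0
    if (any(i & b == 0)) return(Inf)
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * (kl(p, q) + kl(q, p))
}

#' Band relevance from quantization-error distributions
#'
#' Histograms the control and case QE samples on shared equal-width bins
#' (Freedman-Diaconis count on the pooled sample unless `bins` is given),
#' applies additive smoothing, and returns the symmetrized KL divergence of
#' the two histograms. Larger values mean the band's QE distributions are
#' more separable, hence the band is more discriminative.
#'
#' @param qe_control,qe_case Non-empty numeric QE vectors (or QE tibbles
#'   from [quantization_errors()], whose `qe` column is used).
#' @param bins Number of shared histogram bins; default Freedman-Diaconis
#'   on the pooled sample.
#' @param smooth Additive smoothing mass per bin before renormalization.
#' @return Symmetrized KL divergence in nats.
#' @export
band_relevance <- function(qe_control, qe_case, bins = NULL, smooth = 1e-9) {
  pick <- function(v) if (is.data.frame(v)) v$qe else v
  a <- pick(qe_control); b <- pick(qe_case)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both QE sets must be non-empty", call. = FALSE)
  }
  pooled <- c(a, b)
  if (is.null(bins)) bins <- max(nclass.FD(pooled), 2L)
  if (bins < 2L) stop("need at least 2 histogram bins", call. = FALSE)
  rng <- range(pooled)
  if (diff(rng) == 0) {
    stop("degenerate QE distributions: all values identical", call. = FALSE)
  }
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  hist_p <- function(v) {
    cnt <- tabulate(pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1L),
                         bins), nbins = bins)
    p <- cnt + smooth
    p / sum(p)
  }
  symmetric_kl(hist_p(a), hist_p(b))
}
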