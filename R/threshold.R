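# Bayesian decision threshold on the quantization error.
#
# One-dimensional Gaussian class-conditionals on QE for the normal
# (control, "CN") and anomaly (case, "DD") classes, with priors estimated
# from the training frequencies. The decision threshold is the QE value at
# which the two posteriors cross between the class means; above it a sample
# is classified as an anomaly.

#' Fit the Bayesian quantization-error threshold
#'
#' Estimates Gaussian class-conditional densities of the quantization error
#' for the control and case classes, with class priors from the observed
#' frequencies, and computes the decision threshold `tau`: the QE at which
#' the posterior probabilities of the two classes are equal, located between
#' the class means. With equal variances and equal priors this is exactly
#' the midpoint of the means.
#'
#' @param qe Numeric vector of quantization errors (or a tibble from
#'   [quantization_errors()] with a `group` column; then `labels` may be
#'   omitted).
#' @param labels Factor/character vector with values `"control"` and
#'   `"case"`, one per element of `qe`; both classes need >= 2 samples.
#' @param priors Optional named numeric `c(control = , case = )` overriding
#'   the empirical priors (must sum to 1).
#' @return An object of class `qe_threshold` with per-class means, standard
#'   deviations, priors, and the threshold `tau`.
#' @export
fit_qe_threshold <- function(qe, labels = NULL, priors = NULL) {
  if (is.data.frame(qe)) {
    if (is.null(labels)) labels <- qe$group
    qe <- qe$qe
  }
  labels <- as.character(labels)
  stopifnot(length(qe) == length(labels))
  if (!all(labels %in% c("control", "case"))) {
    stop("labels must be 'control' or 'case'", call. = FALSE)
  }
  if (any(!is.finite(qe))) stop("non-finite quantization errors", call. = FALSE)
  split_qe <- split(qe, factor(labels, levels = c("control", "case")))
  n <- vapply(split_qe, length, integer(1))
  if (any(n < 2L)) {
    stop("need at least 2 samples per class (got ", n[1], " control, ",
         n[2], " case)", call. = FALSE)
  }
  m <- vapply(split_qe, mean, numeric(1))
  s <- vapply(split_qe, sd, numeric(1))
  if (any(s <= 0)) {
    stop("zero QE variance in a class; the Gaussian model is degenerate ",
         "(add samples or jitter)", call. = FALSE)
  }
  if (is.null(priors)) {
    priors <- n / sum(n)
  } else {
    stopifnot(all(c("control", "case") %in% names(priors)))
    priors <- priors[c("control", "case")]
    if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1", call. = FALSE)
  }
  tau <- posterior_crossing(m, s, priors)
  structure(
    list(means = m, sds = s, priors = priors, n = n, tau = tau,
         qe = qe, labels = labels),
    class = "qe_threshold"
  )
}

# QE value between the class means where the two posteriors are equal.
posterior_crossing <- function(m, s, priors) {
  m1 <- m[["control"]]; m2 <- m[["case"]]
  s1 <- s[["control"]]; s2 <- s[["case"]]
  # log P(CN|x) - log P(DD|x) = 0 expands to a quadratic A x^2 + B x + C0
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m2 / s2^2
  C0 <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) +
    log(priors[["control"]] * s2 / (priors[["case"]] * s1))
  lo <- min(m1, m2); hi <- max(m1, m2)
  if (abs(A) < 1e-14) {
    root <- -C0 / B
    return(unname(root))
  }
  disc <- B^2 - 4 * A * C0
  if (disc < 0) {
    # posteriors never cross analytically; fall back to the point of
    # closest approach between the means
    f <- function(x) A * x^2 + B * x + C0
    return(stats::optimize(function(x) abs(f(x)), c(lo, hi))$minimum)
  }
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  inside <- roots >= lo & roots <= hi
  if (any(inside)) {
    return(unname(roots[inside][1L]))
  }
  # no crossing between the means: take the root nearest the interval
  unname(roots[which.min(pmin(abs(roots - lo), abs(roots - hi)))])
}

#' @export
print.qe_threshold <- function(x, ...) {
  cat(sprintf(
    "<qe_threshold> tau = %.4g | control: N(%.4g, %.4g^2) x %.2f | case: N(%.4g, %.4g^2) x %.2f\n",
    x$tau, x$means[["control"]], x$sds[["control"]], x$priors[["control"]],
    x$means[["case"]], x$sds[["case"]], x$priors[["case"]]))
  invisible(x)
}

#' Posterior probability of the anomaly class
#'
#' `P(case | qe)` under the fitted two-Gaussian mixture, with the marginal
#' `P(qe)` computed as the prior-weighted mixture of the class
#' conditionals. Posteriors of the two classes sum to 1.
#'
#' @param model A `qe_threshold`.
#' @param qe Numeric vector of quantization errors.
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_case <- function(model, qe) {
  stopifnot(inherits(model, "qe_threshold"))
  f_cn <- model$priors[["control"]] *
    dnorm(qe, model$means[["control"]], model$sds[["control"]])
  f_dd <- model$priors[["case"]] *
    dnorm(qe, model$means[["case"]], model$sds[["case"]])
  # guard against 0/0 underflow far in the tails: decide by the nearer mean
  # on the standardized scale
  post <- f_dd / (f_cn + f_dd)
  deg <- !is.finite(post) | (f_cn + f_dd) == 0
  if (any(deg)) {
    z_cn <- abs(qe[deg] - model$means[["control"]]) / model$sds[["control"]]
    z_dd <- abs(qe[deg] - model$means[["case"]]) / model$sds[["case"]]
    post[deg] <- ifelse(z_dd < z_cn, 1, 0)
  }
  unname(post)
}

#' Classify samples by quantization error
#'
#' A sample is an anomaly (`"case"`) iff its QE strictly exceeds the fitted
#' threshold; a QE exactly at the threshold counts as `"control"` (boundary
#' convention). The posterior of the anomaly class is reported for ROC
#' construction.
#'
#' @param model A `qe_threshold`.
#' @param qe Finite numeric vector of quantization errors.
#' @return Tibble with `qe`, `p_case`, `label`.
#' @export
classify_qe <- function(model, qe) {
  stopifnot(inherits(model, "qe_threshold"))
  if (any(!is.finite(qe))) stop("non-finite quantization errors", call. = FALSE)
  tibble(
    qe = qe,
    p_case = posterior_case(model, qe),
    label = ifelse(qe > model$tau, "case", "control")
  )
}

#' @describeIn fit_qe_threshold Per-class parameter tibble.
#' @param x A `qe_threshold`.
#' @param ... Unused.
#' @export
tidy.qe_threshold <- function(x, ...) {
  tibble(class = c("control", "case"),
         n = unname(x$n), mean = unname(x$means), sd = unname(x$sds),
         prior = unname(x$priors))
}

#' @describeIn fit_qe_threshold One-row model summary.
#' @export
glance.qe_threshold <- function(x, ...) {
  tibble(tau = x$tau, mean_control = x$means[["control"]],
         mean_case = x$means[["case"]], sd_control = x$sds[["control"]],
         sd_case = x$sds[["case"]], prior_case = x$priors[["case"]])
}

#' @export
autoplot.qe_threshold <- function(object, ...) {
  df <- tibble(qe = object$qe, group = object$labels)
  ggplot(df, aes(x = .data$qe, fill = .data$group)) +
    geom_density(alpha = 0.4) +
    geom_vline(xintercept = object$tau, linetype = "dashed") +
    labs(x = "quantization error", y = "density",
         title = sprintf("QE class densities (tau = %.3g)", object$tau)) +
    theme_minimal()
}
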