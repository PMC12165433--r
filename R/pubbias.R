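#' @name pubbias
#' @title Publication-bias detection and correction
#' @description
#' Two conventional corrections, composable with any estimator in the
#' suite.  Trim-and-fill symmetrizes the funnel plot (precision
#' \eqn{1/se^2} against effect size) by iteratively trimming the most
#' extreme effects on the suppressed side's mirror, re-centering, and
#' finally filling mirrored pseudo-observations.  PET-PEESE regresses
#' effects on the standard error (detection) and on the squared standard
#' error (correction), taking the latter's intercept as the bias-adjusted
#' mean: the limit of an infinitely precise study.
NULL

# rank-based estimators of the number of suppressed studies
# (L0 and R0 of the standard trim-and-fill procedure)
.k0_estimate <- function(dev, estimator = c("L0", "R0")) {
  estimator <- match.arg(estimator)
  n <- length(dev)
  ranks <- rank(abs(dev), ties.method = "first")
  if (estimator == "L0") {
    Tn <- sum(ranks[dev > 0])
    k0 <- (4 * Tn - n * (n + 1)) / (2 * n - 1)
  } else {
    # gamma*: length of the rightmost run of positive deviations among
    # the largest absolute ranks
    ord <- order(ranks, decreasing = TRUE)
    run <- 0
    for (j in ord) {
      if (dev[j] > 0) run <- run + 1 else break
    }
    k0 <- run - 1
  }
  max(0L, as.integer(round(k0)))
}

.pool_ivw <- function(y, v) {
  w <- 1 / v
  est <- sum(w * y) / sum(w)
  list(estimate = est, variance = 1 / sum(w))
}

#' Trim-and-fill correction
#'
#' Iterates (estimate center, estimate the suppressed-study count k0 from
#' signed ranks, trim the k0 most extreme effects on the heavy side)
#' until k0 stabilizes, then fills mirror-image pseudo-observations about
#' the corrected center and re-pools the filled set.
#'
#' @param effects Numeric vector of effect estimates (>= 3).
#' @param variances Their variances (squared standard errors).
#' @param side `"auto"` (infer the heavy side from the skewness of the
#'   effects around the pooled center: right-skewed funnels are trimmed
#'   on the right), `"right"` (suppression on the left, excess on the
#'   right), or `"left"`.
#' @param estimator `"L0"` (default) or `"R0"` rank statistic.
#' @param pooling Function `(y, v) -> list(estimate, variance)` used to
#'   center and to pool the filled set; default fixed-effect
#'   inverse-variance.
#' @param max_iter Iteration cap.
#' @return List: `estimate`, `se`, `k0`, `side`, `filled` (data frame of
#'   pseudo-observations), `iterations`.
#' @export
trim_and_fill <- function(effects, variances, side = c("auto", "left",
                                                       "right"),
                          estimator = c("L0", "R0"), pooling = .pool_ivw,
                          max_iter = 50) {
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  n <- length(effects)
  stopifnot(n >= 3, length(variances) == n, all(variances > 0))
  if (side == "auto") {
    c0 <- pooling(effects, variances)$estimate
    m3 <- mean((effects - c0)^3)
    side <- if (is.finite(m3) && m3 < 0) "left" else "right"
  }
  # work on a flipped scale so suppression is always on the left
  flip <- if (side == "left") -1 else 1
  y <- flip * effects
  v <- variances
  k0 <- 0L
  ord <- order(y)
  y <- y[ord]; v <- v[ord]
  it <- 0
  repeat {
    it <- it + 1
    if (it > max_iter)
      stop("trim-and-fill did not converge in ", max_iter, " iterations")
    keep <- if (k0 > 0) seq_len(n - k0) else seq_len(n)
    center <- pooling(y[keep], v[keep])$estimate
    k0_new <- .k0_estimate(y - center, estimator)
    if (k0_new >= n) stop("estimated number of missing studies (", k0_new,
                          ") is not smaller than the number of effects")
    if (k0_new == k0) break
    k0 <- k0_new
  }
  if (k0 > 0) {
    trimmed <- seq(n - k0 + 1, n)
    fill_y <- 2 * center - y[trimmed]
    fill_v <- v[trimmed]
    yy <- c(y, fill_y); vv <- c(v, fill_v)
  } else {
    yy <- y; vv <- v
    fill_y <- numeric(0); fill_v <- numeric(0)
  }
  pooled <- pooling(yy, vv)
  list(estimate = flip * pooled$estimate,
       se = sqrt(pooled$variance),
       k0 = k0, side = side,
       filled = data.frame(effect = flip * fill_y, variance = fill_v),
       iterations = it)
}

#' Trim-and-fill applied to a two-stage random-effects fit
#'
#' Applies the funnel correction at the group level: the first-stage
#' group estimates \eqn{\hat Y_i} with their fitted variances
#' \eqn{\hat v_i} form the funnel (within-group correlation would break
#' the funnel's independence assumption at observation level), and the
#' filled set is re-pooled by inverse variance.  Observation-level mode
#' is available via `level = "observation"`.
#'
#' @param dataset A [meta_dataset].
#' @param variant,rho Passed to [fit_2sre()].
#' @param level `"group"` (default) or `"observation"`.
#' @param ... Passed to [trim_and_fill()].
#' @return A [meta_estimate] with `diagnostics$k0` and
#'   `diagnostics$trimfill`.
#' @export
trim_and_fill_2sre <- function(dataset, variant = "equal", rho = 0.5,
                               level = c("group", "observation"), ...) {
  level <- match.arg(level)
  fit <- fit_2sre(dataset, variant = variant, rho = rho, se = "none")
  if (level == "group") {
    tf <- trim_and_fill(fit$group_estimates,
                        fit$diagnostics$group_variances, ...)
  } else {
    tf <- trim_and_fill(dataset$y, dataset$se^2, ...)
  }
  out <- fit
  out$estimate <- tf$estimate
  out$se <- tf$se
  out$se_method <- "analytic"
  out$weights <- NULL
  out$method_label <- paste0(fit$method_label, " T&F")
  out$diagnostics <- c(fit$diagnostics,
                       list(k0 = tf$k0, trimfill = tf, level = level))
  out
}

# weighted regression of y on columns Z with cluster-robust inference
.pb_regression <- function(dataset, Z, weights) {
  X <- cbind("(Intercept)" = 1, Z)
  w <- weights / sum(weights)
  beta <- .wls(X, dataset$y, w)
  V <- .cluster_robust_vcov(X, dataset$y, w, beta, dataset$group_id)
  list(beta = stats::setNames(beta, colnames(X)),
       se = stats::setNames(sqrt(pmax(diag(V), 0)), colnames(X)))
}

.resolve_pb_weights <- function(dataset, weighting) {
  if (is.numeric(weighting)) return(weighting)
  switch(weighting,
         ivw = 1 / dataset$se^2,
         none = rep(1, nrow(dataset)),
         stop("unknown weighting: ", weighting))
}

#' Precision-effect test (PET)
#'
#' Weighted regression of the effects on a constant and the standard
#' errors; a slope on `se` distinguishable from zero (two-sided 5%,
#' cluster-robust) is read as evidence of publication bias.
#'
#' @param dataset A [meta_dataset] whose `se` varies.
#' @param weighting `"ivw"` (default), `"none"`, or a numeric weight
#'   vector.
#' @param alpha Significance level of the detection rule.
#' @return List: `intercept`, `slope`, `t`, `detected`, `se_slope`.
#' @export
pet <- function(dataset, weighting = "ivw", alpha = 0.05) {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (stats::sd(dataset$se) == 0)
    stop("standard errors are constant; PET regressor is collinear")
  w <- .resolve_pb_weights(dataset, weighting)
  reg <- .pb_regression(dataset, cbind(se = dataset$se), w)
  t <- reg$beta[["se"]] / reg$se[["se"]]
  list(intercept = reg$beta[["(Intercept)"]], slope = reg$beta[["se"]],
       t = t, se_slope = reg$se[["se"]],
       detected = abs(t) > stats::qnorm(1 - alpha / 2))
}

#' Precision-effect estimate with standard error (PEESE)
#'
#' Weighted regression of the effects on a constant and the squared
#' standard errors; the intercept is the corrected mean effect (the
#' extrapolation to a hypothetical infinitely precise study).
#'
#' @inheritParams pet
#' @return List: `estimate` (corrected intercept), `se` (robust),
#'   `slope`.
#' @export
peese <- function(dataset, weighting = "ivw") {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (stats::sd(dataset$se) == 0)
    stop("standard errors are constant; PEESE regressor is collinear")
  w <- .resolve_pb_weights(dataset, weighting)
  reg <- .pb_regression(dataset, cbind(se2 = dataset$se^2), w)
  list(estimate = reg$beta[["(Intercept)"]],
       se = reg$se[["(Intercept)"]], slope = reg$beta[["se2"]])
}

#' Conditional PET-PEESE correction
#'
#' Runs the precision-effect test; if it detects selection, reports the
#' PEESE intercept as the corrected estimate, otherwise the uncorrected
#' weighted mean (or the PET intercept, per `fallback`).  The decision
#' path is recorded.
#'
#' @inheritParams pet
#' @param fallback What to report when PET does not fire:
#'   `"uncorrected"` (the weighted mean under `weighting`) or `"pet"`
#'   (the PET intercept).
#' @return A [meta_estimate] with `diagnostics$pet` and
#'   `diagnostics$decision`.
#' @export
pet_peese <- function(dataset, weighting = "ivw", alpha = 0.05,
                      fallback = c("uncorrected", "pet")) {
  fallback <- match.arg(fallback)
  p <- pet(dataset, weighting = weighting, alpha = alpha)
  if (p$detected) {
    pe <- peese(dataset, weighting = weighting)
    est <- pe$estimate; se <- pe$se; decision <- "peese"
  } else if (fallback == "pet") {
    est <- p$intercept; se <- NA_real_; decision <- "pet-intercept"
  } else {
    w <- .resolve_pb_weights(dataset, weighting)
    w <- w / sum(w)
    est <- sum(w * dataset$y)
    res0 <- new_meta_estimate(
      estimate = est,
      weights = data.frame(group_id = dataset$group_id,
                           row = seq_len(nrow(dataset)), w = w),
      n_groups = n_groups(dataset), n_obs = nrow(dataset),
      method_label = "uncorrected")
    se <- if (n_groups(dataset) >= 2) robust_se(dataset, res0) else NA_real_
    decision <- "uncorrected"
  }
  new_meta_estimate(
    estimate = est, se = se,
    se_method = if (is.na(se)) "unavailable" else "robust",
    n_groups = n_groups(dataset), n_obs = nrow(dataset),
    method_label = "PET-PEESE",
    diagnostics = list(pet = p, decision = decision))
}
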