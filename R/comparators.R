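#' @name comparators
#' @title Comparator meta-analysis estimators
#' @description
#' Re-implementations of the standard estimators the two-stage
#' random-effects estimator is benchmarked against in the Monte Carlo
#' harness: unweighted means, fixed-effect inverse-variance weighting,
#' DerSimonian-Laird random effects, a dependent-observation aggregator,
#' correlated- and hierarchical-effects working models from the robust
#' variance estimation literature, and a multilevel REML estimator with a
#' known sampling covariance.  All conform to the uniform interface
#' `(meta_dataset, options) -> meta_estimate` with convex weights.
NULL

.finish_comparator <- function(dataset, w, label, components = NULL,
                               diagnostics = list(), robust = TRUE) {
  idx <- .group_index(dataset)
  Yi <- vapply(idx, function(rows) {
    ww <- w[rows]; sum(ww / sum(ww) * dataset$y[rows])
  }, numeric(1))
  res <- new_meta_estimate(
    estimate = sum(w * dataset$y), se = NA_real_, se_method = "none",
    group_estimates = Yi,
    weights = data.frame(group_id = dataset$group_id,
                         row = seq_len(nrow(dataset)), w = w),
    components = components, n_groups = length(idx),
    n_obs = nrow(dataset), method_label = label,
    diagnostics = diagnostics)
  if (robust && length(idx) >= 2) {
    res$se <- robust_se(dataset, res)
    res$se_method <- "robust"
  }
  res
}

#' Simple mean estimator
#'
#' Unweighted mean of all observations.
#' @param dataset A [meta_dataset].
#' @return A [meta_estimate].
#' @export
simple_mean <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  n <- nrow(dataset)
  .finish_comparator(dataset, rep(1 / n, n), "simple mean")
}

#' Group means estimator
#'
#' Unweighted mean of the within-group unweighted means; every group gets
#' equal weight so \eqn{w_{ij} = 1/(I J_i)}.
#' @param dataset A [meta_dataset].
#' @return A [meta_estimate].
#' @export
group_means <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  idx <- .group_index(dataset)
  I <- length(idx)
  w <- numeric(nrow(dataset))
  for (rows in idx) w[rows] <- 1 / (I * length(rows))
  .finish_comparator(dataset, w, "group means")
}

#' Fixed-effect inverse-variance estimator
#'
#' Weights proportional to \eqn{1/se^2}, ignoring all non-sampling
#' heterogeneity and grouping.
#' @param dataset A [meta_dataset].
#' @return A [meta_estimate].
#' @export
fe_ivw <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  w <- 1 / dataset$se^2
  .finish_comparator(dataset, w / sum(w), "fixed-effect IVW")
}

#' DerSimonian-Laird random-effects estimator
#'
#' For datasets with one observation per group: method-of-moments
#' \eqn{\tau^2 = \max(0, (Q - df) / C)} from Cochran's Q under
#' fixed-effect weights, then weights \eqn{\propto 1/(\tau^2 + se^2)}.
#' Multi-observation groups must first be collapsed with
#' [mad_aggregate()].
#' @param dataset A [meta_dataset] of singleton groups.
#' @return A [meta_estimate]; `diagnostics$tau_sq` carries the
#'   heterogeneity estimate.
#' @export
dl_re <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (any(group_sizes(dataset) > 1))
    stop("DerSimonian-Laird expects one observation per group; ",
         "aggregate dependent observations first with mad_aggregate()")
  y <- dataset$y; v <- dataset$se^2
  wf <- 1 / v
  yf <- sum(wf * y) / sum(wf)
  Q <- sum(wf * (y - yf)^2)
  df <- length(y) - 1
  C <- sum(wf) - sum(wf^2) / sum(wf)
  tau_sq <- max(0, (Q - df) / C)
  w <- 1 / (tau_sq + v)
  .finish_comparator(dataset, w / sum(w), "DerSimonian-Laird RE",
                     diagnostics = list(tau_sq = tau_sq, Q = Q))
}

#' Aggregate dependent observations within groups
#'
#' Collapses each group to its unweighted mean with composite variance
#' \eqn{\frac{1}{J^2}\big(\sum_j se_j^2 +
#' \hat\rho\sum_{j\neq k} se_j se_k\big)}, given a user-specified
#' within-group sampling-error correlation.  The result is a singleton
#' dataset suitable for [dl_re()].
#'
#' @param dataset A [meta_dataset].
#' @param rho_hat Assumed within-group correlation, |rho| < 1 (the
#'   boundary value 1 is accepted for the perfect-correlation limit).
#' @return A [meta_dataset] with one row per group.
#' @export
mad_aggregate <- function(dataset, rho_hat = 0.5) {
  stopifnot(inherits(dataset, "meta_dataset"), abs(rho_hat) <= 1)
  idx <- .group_index(dataset)
  rows <- lapply(names(idx), function(gid) {
    r <- idx[[gid]]
    J <- length(r)
    se <- dataset$se[r]
    v <- (sum(se^2) + rho_hat * (sum(se)^2 - sum(se^2))) / J^2
    data.frame(group_id = gid, y = mean(dataset$y[r]), se = sqrt(v))
  })
  meta_dataset(do.call(rbind, rows), units = attr(dataset, "units"))
}

#' Correlated-effects working model
#'
#' Approximate inverse-variance weights for correlated effect sizes:
#' each group's composite variance is the variance of its unweighted mean
#' under a group-constant sampling variance \eqn{\bar v_i} and the
#' user-specified correlation, \eqn{\bar v_i (1 + (J_i - 1)\hat\rho)/J_i};
#' a DerSimonian-Laird-type method-of-moments \eqn{\tau^2} on the
#' composites supplies the between-group component; within a group the
#' weight is split equally.  This is the standard approximate
#' correlated-effects scheme of the robust-variance-estimation
#' literature, not a numerical replica of any particular package.
#'
#' @param dataset A [meta_dataset].
#' @param rho_hat Assumed within-group correlation.
#' @return A [meta_estimate] with robust SE.
#' @export
corr_weights <- function(dataset, rho_hat = 0.5) {
  stopifnot(inherits(dataset, "meta_dataset"), abs(rho_hat) <= 1)
  idx <- .group_index(dataset)
  vbar <- vapply(idx, function(r) mean(dataset$se[r]^2), numeric(1))
  J <- vapply(idx, length, numeric(1))
  Vcomp <- vbar * (1 + (J - 1) * rho_hat) / J
  ybar <- vapply(idx, function(r) mean(dataset$y[r]), numeric(1))
  # DL-type tau^2 on the composites
  wf <- 1 / Vcomp
  yf <- sum(wf * ybar) / sum(wf)
  Q <- sum(wf * (ybar - yf)^2)
  C <- sum(wf) - sum(wf^2) / sum(wf)
  tau_sq <- max(0, (Q - (length(idx) - 1)) / C)
  Wg <- 1 / (Vcomp + tau_sq)
  Wg <- Wg / sum(Wg)
  w <- numeric(nrow(dataset))
  for (i in seq_along(idx)) w[idx[[i]]] <- Wg[i] / J[i]
  .finish_comparator(dataset, w, "correlated effects (CORR)",
                     diagnostics = list(tau_sq = tau_sq, rho_hat = rho_hat,
                                        scheme = "group-constant variance"))
}

#' Hierarchical-effects working model
#'
#' Two-level random-effects weights assuming independent sampling errors
#' (\eqn{\rho = 0}) and a common within-group non-sampling variance: this
#' is the two-stage estimator with the pooled (`"equal"`) variance variant
#' and no sampling-error correlation.  Variance components may be supplied
#' to override estimation.
#'
#' @param dataset A [meta_dataset].
#' @param known_components Optional list with `sigma_eta_sq` and
#'   `sigma_mu_sq` to force the variance components.
#' @return A [meta_estimate] with robust SE.
#' @export
hier_weights <- function(dataset, known_components = NULL) {
  fit <- if (is.null(known_components))
    fit_2sre(dataset, variant = "equal", rho = 0)
  else
    fit_2sre(dataset, variant = "true", rho = 0,
             known_components = known_components)
  fit$method_label <- "hierarchical effects (HIER)"
  fit
}

#' Multilevel REML estimator with known sampling covariance
#'
#' Estimates a single between-group variance \eqn{\sigma_\eta^2} by
#' restricted maximum likelihood under normality, treating the sampling
#' covariance as known block-diagonal (diagonal \eqn{se^2}, off-diagonal
#' \eqn{\hat\rho\, se_j se_k} within groups), with no observation-level
#' non-sampling component.  The point estimate is GLS under the fitted
#' covariance.
#'
#' @param dataset A [meta_dataset] with at least two groups.
#' @param rho_hat Assumed within-group sampling-error correlation.
#' @param upper Upper bound for the variance search (default: 100 times
#'   the sample variance of `y`).
#' @return A [meta_estimate]; `diagnostics$sigma_eta_sq` holds the REML
#'   estimate.
#' @export
reml_multilevel <- function(dataset, rho_hat = 0.5, upper = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  idx <- .group_index(dataset)
  I <- length(idx)
  if (I < 2) stop("REML requires at least two groups")
  n <- nrow(dataset)
  y <- dataset$y
  if (is.null(upper)) upper <- max(1e-4, 100 * stats::var(y))
  # per-group sampling covariance blocks (no mu component)
  blocks <- lapply(idx, function(r) .group_cov(0, dataset$se[r], rho_hat))

  neg_restricted_ll <- function(s_eta_sq) {
    ldV <- 0; xvx <- 0; xvy <- 0; yvy <- 0
    for (i in seq_len(I)) {
      r <- idx[[i]]
      V <- blocks[[i]] + s_eta_sq  # eta adds s_eta_sq to every entry
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      ldV <- ldV + 2 * sum(log(diag(ch)))
      o <- backsolve(ch, forwardsolve(t(ch), rep(1, length(r))))
      z <- backsolve(ch, forwardsolve(t(ch), y[r]))
      xvx <- xvx + sum(o)
      xvy <- xvy + sum(o * y[r])
      yvy <- yvy + sum(z * y[r])
    }
    mu <- xvy / xvx
    0.5 * (ldV + log(xvx) + (yvy - 2 * mu * xvy + mu^2 * xvx))
  }
  opt <- stats::optimize(neg_restricted_ll, c(0, upper))
  if (!is.finite(opt$objective))
    stop("REML optimization failed; likelihood non-finite over the search ",
         "interval")
  s_eta_sq <- opt$minimum
  # boundary polish: compare against exactly 0
  if (neg_restricted_ll(0) <= opt$objective) s_eta_sq <- 0
  # GLS weights under fitted covariance
  w <- numeric(n)
  for (i in seq_len(I)) {
    r <- idx[[i]]
    V <- blocks[[i]] + s_eta_sq
    w[r] <- solve(V, rep(1, length(r)))
  }
  w <- w / sum(w)
  .finish_comparator(dataset, w, "multilevel REML",
                     diagnostics = list(sigma_eta_sq = s_eta_sq,
                                        rho_hat = rho_hat))
}
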