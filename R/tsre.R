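#' @name tsre
#' @title Two-stage random-effects estimator internals
#' @description
#' The estimator models each observation as
#' \deqn{y_{ij} = Y + \eta_i + \mu_{ij} + \varepsilon_{ij},}
#' with a group-level non-sampling error \eqn{\eta_i} (variance
#' \eqn{\sigma_\eta^2}), an observation-level non-sampling error
#' \eqn{\mu_{ij}} (variance \eqn{\sigma_{\mu,i}^2}), and a sampling error
#' \eqn{\varepsilon_{ij}} whose standard deviation equals the reported
#' standard error and which may be correlated within a group with
#' correlation \eqn{\rho}.  Stage one forms variance-minimizing convex
#' weights \eqn{g_{ij}} within each group; stage two weights the group
#' estimates by the inverse of their unconditional variances.  All
#' variance components are estimated by the method of moments, so no
#' distributional assumptions are required.
NULL

# split into per-group index lists, preserving first-appearance order
.group_index <- function(dataset) {
  ids <- unique(dataset$group_id)
  lapply(stats::setNames(ids, ids), function(g) which(dataset$group_id == g))
}

# within-group covariance of mu + eps: diagonal sigma_mu^2 + se^2,
# off-diagonal rho * se_j * se_k
.group_cov <- function(sigma_mu_sq, se, rho) {
  S <- rho * (se %o% se)
  diag(S) <- sigma_mu_sq + se^2
  S
}

#' Method-of-moments within-group variance for one group
#'
#' Estimates the observation-level non-sampling variance
#' \eqn{\sigma_{\mu,i}^2} for a group with at least two observations: the
#' within-group sample variance of the effects (less the sample variance of
#' the fitted values in meta-regression mode), minus the mean squared
#' sampling error, plus the correlation adjustment
#' \eqn{\frac{1}{J(J-1)}\sum_{j\neq k}\rho\, se_j se_k}.  The untruncated
#' statistic is unbiased for \eqn{\sigma_{\mu,i}^2} under the model's error
#' decomposition; negative values are truncated at zero.
#'
#' @param y Effect sizes of the group (length >= 2).
#' @param se Their standard errors.
#' @param rho Assumed within-group sampling-error correlation, |rho| < 1.
#' @param fitted Optional fitted values \eqn{x_{ij}\hat\beta} for
#'   meta-regression mode.
#' @return List: `value` (truncated at 0), `raw`, `truncated` flag.
#' @export
estimate_sigma_mu_group <- function(y, se, rho = 0, fitted = NULL) {
  J <- length(y)
  if (J < 2) stop("sigma_mu cannot be estimated for a singleton group")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  stopifnot(length(se) == J)
  s2y <- sum((y - mean(y))^2) / (J - 1)
  if (!is.null(fitted)) {
    stopifnot(length(fitted) == J)
    s2y <- (sum((y - mean(y))^2) - sum((fitted - mean(fitted))^2)) / (J - 1)
  }
  cross <- rho * (sum(se)^2 - sum(se^2))  # sum_{j != k} rho se_j se_k
  raw <- s2y - mean(se^2) + cross / (J * (J - 1))
  list(value = max(0, raw), raw = raw, truncated = raw < 0)
}

#' Resolve per-group within-group variances across variants
#'
#' Singleton groups cannot supply their own \eqn{\hat\sigma_{\mu,i}^2};
#' under `variant = "free"` they receive the average of the non-singleton
#' groups' \eqn{\hat\sigma_{\mu,i}} (averaged on the sigma scale, then
#' squared).  Under `variant = "equal"` a single pooled value — the
#' degrees-of-freedom-weighted mean of the raw per-group estimates — is
#' assigned to every group.
#'
#' @param per_group Named numeric vector of raw (truncated) per-group
#'   estimates, `NA` for singleton groups.
#' @param J Named integer vector of group sizes (same order).
#' @param variant `"free"` or `"equal"`.
#' @param fill_scale `"sigma"` (default, average on the SD scale) or
#'   `"sigma_sq"` for the singleton fill under `"free"`.
#' @return List: `sigma_mu_sq` (complete named vector), `singleton_fill`
#'   (on the variance scale; `NA` if no singletons), `all_singleton` flag.
#' @export
resolve_sigma_mu <- function(per_group, J, variant = c("free", "equal"),
                             fill_scale = c("sigma", "sigma_sq")) {
  variant <- match.arg(variant)
  fill_scale <- match.arg(fill_scale)
  stopifnot(length(per_group) == length(J))
  non_single <- J >= 2
  if (!any(non_single)) {
    warning("all groups are singletons: sigma_mu set to 0 for all groups; ",
            "the estimator degenerates to a between-group random-effects model")
    return(list(sigma_mu_sq = stats::setNames(rep(0, length(J)), names(J)),
                singleton_fill = 0, all_singleton = TRUE))
  }
  out <- per_group
  fill <- NA_real_
  if (variant == "equal") {
    df <- pmax(J - 1L, 0L)
    pooled <- sum(df[non_single] * per_group[non_single]) / sum(df[non_single])
    out[] <- pooled
    fill <- pooled
  } else {
    if (any(!non_single)) {
      fill <- if (fill_scale == "sigma")
        mean(sqrt(per_group[non_single]))^2
      else mean(per_group[non_single])
      out[!non_single] <- fill
    }
  }
  list(sigma_mu_sq = out, singleton_fill = fill, all_singleton = FALSE)
}

#' Within-group variance-minimizing weights
#'
#' Computes the convex weights \eqn{g_i} minimizing the variance of the
#' group estimate \eqn{\hat Y_i = \sum_j g_{ij} y_{ij}} under the
#' within-group covariance with diagonal \eqn{\sigma_{\mu,i}^2 + se_j^2}
#' and off-diagonal \eqn{\rho\, se_j se_k}.  The weights are obtained from
#' the fixed-point form \eqn{g = (I - B)^{-1} A}, where \eqn{A} is the
#' normalized conditional inverse-variance vector and \eqn{B} the rank-one
#' correlation correction; this is algebraically the normalized
#' \eqn{\Sigma^{-1} 1} GLS solution.
#'
#' @param sigma_mu_sq Within-group non-sampling variance (scalar, >= 0).
#' @param se Standard errors of the group's observations (> 0).
#' @param rho Assumed sampling-error correlation, |rho| < 1.
#' @return Numeric weight vector `g` (sums to 1) with attributes `"A"`
#'   (conditional inverse-variance vector) and `"B"` (correlation
#'   correction matrix).
#' @export
within_group_weights <- function(sigma_mu_sq, se, rho = 0) {
  stopifnot(sigma_mu_sq >= 0, all(se > 0), abs(rho) < 1)
  J <- length(se)
  if (J == 1)
    return(structure(1, A = 1, B = matrix(0, 1, 1)))
  d <- sigma_mu_sq + (1 - rho) * se^2    # conditional variances
  if (any(d <= 0))
    stop("degenerate within-group conditional variance (group system singular)")
  A <- (1 / d) / sum(1 / d)
  S1 <- sum(se / d)
  S2 <- sum(1 / d)
  B <- (rho * (S1 / (d * S2) - se / d)) %o% se
  M <- diag(J) - B
  g <- tryCatch(solve(M, A), error = function(e)
    stop("singular within-group weight system: ", conditionMessage(e)))
  structure(as.numeric(g), A = A, B = B)
}

#' Group-level estimate
#'
#' Inner product of within-group weights and effects.
#'
#' @param g Weights summing to 1.
#' @param y Effects, same length.
#' @export
group_estimate <- function(g, y) {
  if (length(g) != length(y)) stop("length mismatch between weights and effects")
  sum(g * y)
}

#' Method-of-moments between-group variance
#'
#' The sample variance of the group estimates minus the mean of their
#' conditional variances \eqn{g_i'\Sigma_i g_i}; unbiased for
#' \eqn{\sigma_\eta^2} before truncation at zero.
#'
#' @param group_estimates Vector of group estimates (or weighted group
#'   residuals in meta-regression mode), length >= 2.
#' @param cond_vars Conditional variances \eqn{g_i'\Sigma_i g_i}, same
#'   length.
#' @return List: `value`, `raw`, `truncated`.
#' @export
estimate_sigma_eta <- function(group_estimates, cond_vars) {
  I <- length(group_estimates)
  if (I < 2) stop("between-group variance inestimable with a single group")
  stopifnot(length(cond_vars) == I)
  raw <- stats::var(group_estimates) - mean(cond_vars)
  list(value = max(0, raw), raw = raw, truncated = raw < 0)
}

#' Group variances and between-group weights
#'
#' \eqn{v_i = \sigma_\eta^2 + g_i'\Sigma_i g_i}; \eqn{h_i \propto 1/v_i}
#' normalized to sum to 1.
#'
#' @param sigma_eta_sq Between-group variance (>= 0).
#' @param cond_vars Conditional variances of the group estimates.
#' @return List: `v`, `h`.
#' @export
group_variances_and_weights <- function(sigma_eta_sq, cond_vars) {
  v <- sigma_eta_sq + cond_vars
  if (any(v <= 0)) stop("non-positive group variance encountered")
  h <- (1 / v) / sum(1 / v)
  list(v = v, h = h)
}

# core weight engine shared by meta-analysis and meta-regression:
# given per-group sigma_mu_sq and (estimated or known) sigma_eta_sq,
# produce g, cond_vars, v, h, w
.tsre_weights <- function(dataset, idx, sigma_mu_sq, rho, sigma_eta_sq) {
  gl <- vector("list", length(idx))
  cond <- numeric(length(idx))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    se_i <- dataset$se[rows]
    g <- within_group_weights(sigma_mu_sq[i], se_i, rho)
    Sig <- .group_cov(sigma_mu_sq[i], se_i, rho)
    gl[[i]] <- g
    cond[i] <- as.numeric(t(g) %*% Sig %*% g)
  }
  vh <- group_variances_and_weights(sigma_eta_sq, cond)
  w <- numeric(nrow(dataset))
  for (i in seq_along(idx)) w[idx[[i]]] <- gl[[i]] * vh$h[i]
  list(g = gl, cond_vars = cond, v = vh$v, h = vh$h, w = w)
}

# estimate per-group sigma_mu and resolve by variant; `fitted` is the
# optional vector of x'beta for meta-regression mode.  The "free" variant
# truncates each group at 0 (each group's variance is used on its own);
# the "equal" variant pools the *untruncated* estimates and truncates the
# pooled value once — per-group truncation before averaging would bias
# the pooled variance upward because the raw estimates are noisy
.tsre_sigma_mu <- function(dataset, idx, rho, variant, fitted = NULL,
                           fill_scale = "sigma") {
  J <- vapply(idx, length, integer(1))
  vals <- rep(NA_real_, length(idx))
  names(vals) <- names(idx)
  trunc_count <- 0L
  for (i in seq_along(idx)) {
    if (J[i] < 2) next
    rows <- idx[[i]]
    est <- estimate_sigma_mu_group(dataset$y[rows], dataset$se[rows], rho,
                                   fitted = if (is.null(fitted)) NULL
                                            else fitted[rows])
    vals[i] <- if (variant == "equal") est$raw else est$value
    if (est$truncated) trunc_count <- trunc_count + 1L
  }
  res <- resolve_sigma_mu(vals, stats::setNames(J, names(idx)),
                          variant = variant, fill_scale = fill_scale)
  if (variant == "equal") {
    res$pooled_raw <- res$sigma_mu_sq[[1]]
    res$sigma_mu_sq <- pmax(res$sigma_mu_sq, 0)
  }
  res$trunc_count <- trunc_count
  res
}

#' Fit the two-stage random-effects estimator
#'
#' Runs the full feasible sequence: per-group method-of-moments
#' within-group variances, variant resolution (`"free"` per-group,
#' `"equal"` pooled, `"true"` user-supplied), within-group weights
#' \eqn{g}, group estimates \eqn{\hat Y_i}, between-group variance
#' \eqn{\hat\sigma_\eta^2}, group weights \eqn{h \propto 1/v}, and the
#' overall estimate \eqn{\hat Y = \sum_i h_i \hat Y_i}.
#'
#' @param dataset A [meta_dataset].
#' @param variant `"equal"` (pooled within-group variance; recommended
#'   default for datasets of modest size), `"free"` (per-group), or
#'   `"true"` (components supplied via `known_components`; simulation use).
#' @param rho Assumed within-group sampling-error correlation
#'   \eqn{\hat\rho}; default 0.5, the recommended setting for meta-datasets
#'   with multiple estimates per study.
#' @param known_components For `variant = "true"`: list with
#'   `sigma_eta_sq` and `sigma_mu_sq` (per-group named vector, or scalar
#'   recycled).
#' @param se How to compute the standard error: `"robust"`
#'   (cluster-sandwich, default), `"none"`.
#' @return A [meta_estimate].
#' @examples
#' d <- meta_dataset(data.frame(group_id = rep(c("a", "b", "c"), c(3, 2, 1)),
#'                              y = c(9, 10, 11, 8, 12, 10),
#'                              se = c(1, 1, 2, 1, 1, 1.5)))
#' fit_2sre(d, variant = "equal", rho = 0.5)
#' @export
fit_2sre <- function(dataset, variant = c("equal", "free", "true"),
                     rho = 0.5, known_components = NULL,
                     se = c("robust", "none")) {
  stopifnot(inherits(dataset, "meta_dataset"))
  variant <- match.arg(variant)
  se <- match.arg(se)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  idx <- .group_index(dataset)
  I <- length(idx)
  diag_list <- list()

  if (variant == "true") {
    if (is.null(known_components))
      stop("variant = 'true' requires known_components")
    smu <- known_components$sigma_mu_sq
    if (length(smu) == 1) smu <- rep(smu, I)
    smu <- stats::setNames(as.numeric(smu), names(idx))
    seta <- known_components$sigma_eta_sq
    fill <- NA_real_
  } else {
    res <- .tsre_sigma_mu(dataset, idx, rho, variant)
    smu <- res$sigma_mu_sq
    fill <- res$singleton_fill
    diag_list$sigma_mu_truncations <- res$trunc_count
    diag_list$all_singleton <- res$all_singleton
    # untruncated pooled value (the unbiased method-of-moments statistic)
    if (!is.null(res$pooled_raw))
      diag_list$sigma_mu_sq_pooled_raw <- res$pooled_raw
    seta <- NULL  # estimated below
  }

  # within-group stage
  gl <- vector("list", I)
  cond <- numeric(I)
  Yi <- numeric(I)
  for (i in seq_len(I)) {
    rows <- idx[[i]]
    se_i <- dataset$se[rows]
    g <- within_group_weights(smu[i], se_i, rho)
    gl[[i]] <- g
    cond[i] <- as.numeric(t(g) %*% .group_cov(smu[i], se_i, rho) %*% g)
    Yi[i] <- group_estimate(g, dataset$y[rows])
  }
  names(Yi) <- names(idx)

  if (is.null(seta)) {
    if (I >= 2) {
      eta_est <- estimate_sigma_eta(Yi, cond)
      seta <- eta_est$value
      diag_list$sigma_eta_truncated <- eta_est$truncated
      diag_list$sigma_eta_sq_raw <- eta_est$raw
    } else {
      seta <- 0
      diag_list$sigma_eta_truncated <- NA
    }
  }

  vh <- group_variances_and_weights(seta, cond)
  w <- numeric(nrow(dataset))
  for (i in seq_len(I)) w[idx[[i]]] <- gl[[i]] * vh$h[i]
  Yhat <- sum(vh$h * Yi)

  comp <- new_variance_components(
    sigma_eta_sq = seta, sigma_mu_sq = smu, rho = rho,
    variant = variant, singleton_fill = fill, diagnostics = diag_list)

  result <- new_meta_estimate(
    estimate = Yhat, se = NA_real_, se_method = "none",
    group_estimates = Yi,
    weights = data.frame(group_id = dataset$group_id,
                         row = seq_len(nrow(dataset)), w = w),
    components = comp, n_groups = I, n_obs = nrow(dataset),
    method_label = paste0("2SRE-", variant),
    diagnostics = c(diag_list,
                    list(group_variances = as.numeric(vh$v),
                         group_weights = as.numeric(vh$h))))
  if (se == "robust" && I >= 2) {
    result$se <- robust_se(dataset, result)
    result$se_method <- "robust"
  }
  result
}

#' Cluster-robust (sandwich) standard error of a weighted-mean estimator
#'
#' Treats groups as clusters: with fitted per-observation weights
#' \eqn{w_{ij}} summing to one, the CR0 variance is
#' \eqn{\sum_i \big(\sum_j w_{ij}(y_{ij}-\hat Y)\big)^2} with small-sample
#' factor \eqn{I/(I-1)}.
#'
#' @param dataset The [meta_dataset] the estimate was fitted to.
#' @param result A [meta_estimate] carrying per-observation weights.
#' @return The robust standard error.
#' @export
robust_se <- function(dataset, result) {
  stopifnot(inherits(result, "meta_estimate"))
  w <- result$weights$w
  ids <- result$weights$group_id
  I <- length(unique(ids))
  if (I < 2) stop("robust SE requires at least two groups")
  r <- dataset$y - result$estimate
  cluster_sums <- tapply(w * r, ids, sum)
  sqrt(I / (I - 1) * sum(cluster_sums^2))
}

#' Cluster bootstrap standard error
#'
#' Resamples groups (not observations) with replacement, refits the
#' estimator on each replicate — variance components, singleton fills and
#' pooling are re-estimated every time — and reports the standard
#' deviation of the replicate estimates.  Replicates whose resample
#' contains a single distinct source group are skipped and counted.
#'
#' @param dataset A [meta_dataset].
#' @param variant,rho Passed to [fit_2sre()].
#' @param B Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; same seed gives bit-identical results.
#' @param fitter Optional function `(meta_dataset) -> meta_estimate`
#'   overriding the default 2SRE fit (so any estimator in the suite can be
#'   bootstrapped).
#' @return List: `se`, `replicates` (vector of estimates), `skipped`.
#' @export
cluster_bootstrap_se <- function(dataset, variant = "equal", rho = 0.5,
                                 B = 2000, seed = NULL, fitter = NULL) {
  stopifnot(B >= 2)
  idx <- .group_index(dataset)
  I <- length(idx)
  if (I < 2) stop("cluster bootstrap requires at least two groups")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fitter))
    fitter <- function(d) fit_2sre(d, variant = variant, rho = rho,
                                   se = "none")
  ests <- rep(NA_real_, B)
  skipped <- 0L
  ids <- names(idx)
  for (b in seq_len(B)) {
    pick <- sample.int(I, I, replace = TRUE)
    if (length(unique(pick)) < 2) { skipped <- skipped + 1L; next }
    rows <- unlist(idx[pick], use.names = FALSE)
    boot <- as.data.frame(dataset)[rows, , drop = FALSE]
    # relabel so repeated draws of a group count as distinct groups
    boot$group_id <- rep(paste0("b", seq_len(I), ".", ids[pick]),
                         vapply(idx[pick], length, integer(1)))
    bd <- meta_dataset(boot, units = attr(dataset, "units"))
    ests[b] <- suppressWarnings(fitter(bd)$estimate)
  }
  list(se = stats::sd(ests, na.rm = TRUE), replicates = ests,
       skipped = skipped)
}
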