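#' Estimator result container
#'
#' All estimators in the package return a `meta_estimate`: the overall
#' weighted-mean estimate, per-group estimates, per-observation weights,
#' a standard error tagged with how it was obtained, the fitted variance
#' components, and diagnostics (variance truncations, singleton fills).
#'
#' @param estimate Overall point estimate.
#' @param se Standard error (may be `NA` until computed).
#' @param se_method How `se` was obtained (`"robust"`, `"bootstrap"`,
#'   `"analytic"`, ...).
#' @param group_estimates Named numeric vector of per-group estimates.
#' @param weights Data frame with columns `group_id`, `row`, `w`.
#' @param components A `variance_components` object or `NULL`.
#' @param n_groups,n_obs Counts.
#' @param method_label Human-readable estimator name.
#' @param diagnostics List of diagnostic flags/counters.
#' @return An object of class `meta_estimate`.
#' @keywords internal
#' @export
new_meta_estimate <- function(estimate, se = NA_real_, se_method = "none",
                              group_estimates = NULL, weights = NULL,
                              components = NULL, n_groups = NA_integer_,
                              n_obs = NA_integer_, method_label = "",
                              diagnostics = list()) {
  if (!is.null(weights)) {
    real_w <- weights$w[!is.na(weights$row)]
    if (length(real_w) > 0 && abs(sum(real_w) - 1) > 1e-10)
      stop("weights must sum to 1 (got ", format(sum(real_w), digits = 15), ")")
  }
  structure(list(estimate = estimate, se = se, se_method = se_method,
                 group_estimates = group_estimates, weights = weights,
                 components = components, n_groups = n_groups,
                 n_obs = n_obs, method_label = method_label,
                 diagnostics = diagnostics),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s estimate: %s", x$method_label,
              format(x$estimate, digits = digits)))
  if (!is.na(x$se))
    cat(sprintf("  (se = %s, %s)", format(x$se, digits = digits),
                x$se_method))
  cat(sprintf("\n  groups: %s, observations: %s\n",
              x$n_groups, x$n_obs))
  if (!is.null(x$components)) print(x$components, digits = digits)
  invisible(x)
}

#' @export
coef.meta_estimate <- function(object, ...) object$estimate

#' Serialize an estimator result to JSON
#'
#' @param x A [meta_estimate].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
meta_estimate_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "meta_estimate"))
  obj <- list(
    estimate = x$estimate, se = x$se, se_method = x$se_method,
    method_label = x$method_label, n_groups = x$n_groups, n_obs = x$n_obs,
    group_estimates = as.list(x$group_estimates),
    weights = x$weights,
    components = if (is.null(x$components)) NULL else unclass(x$components),
    diagnostics = x$diagnostics)
  if (is.null(path))
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}

#' Variance components container
#'
#' @param sigma_eta_sq Between-group non-sampling variance (>= 0).
#' @param sigma_mu_sq Named per-group within-group non-sampling variances.
#' @param rho Assumed within-group sampling-error correlation(s).
#' @param variant One of `"true"`, `"free"`, `"equal"`.
#' @param singleton_fill Value substituted for singleton groups (sigma
#'   scale), or `NA`.
#' @param diagnostics List: truncation counts etc.
#' @keywords internal
#' @export
new_variance_components <- function(sigma_eta_sq, sigma_mu_sq, rho,
                                    variant, singleton_fill = NA_real_,
                                    diagnostics = list()) {
  stopifnot(sigma_eta_sq >= 0, all(sigma_mu_sq >= 0), all(abs(rho) < 1))
  structure(list(sigma_eta_sq = sigma_eta_sq, sigma_mu_sq = sigma_mu_sq,
                 rho = rho, variant = variant,
                 singleton_fill = singleton_fill,
                 diagnostics = diagnostics),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat(sprintf("  variance components (%s): sigma_eta = %s, sigma_mu in [%s, %s]\n",
              x$variant,
              format(sqrt(x$sigma_eta_sq), digits = digits),
              format(sqrt(min(x$sigma_mu_sq)), digits = digits),
              format(sqrt(max(x$sigma_mu_sq)), digits = digits)))
  invisible(x)
}
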