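#' Build a meta-regression design matrix
#'
#' Assembles the moderator matrix for one of seven standard
#' specifications, optionally augmented with the publication-bias
#' regressors of the precision-effect test (PET: the standard error) or
#' the precision-effect estimate with SE (PEESE: the squared standard
#' error):
#'
#' * `s0` — constant only
#' * `s1` — SP, median
#' * `s2` — SP, median, year
#' * `s3` — SP, median, income
#' * `s4` — SP, median, year, income
#' * `s5` — SP, median, year, SP x year
#' * `s6` — SP, median, income, SP x income
#'
#' Year and income are centered at their observation means, so the
#' constant is interpretable as the predicted effect for a
#' revealed-preference mean observation at the average data year / income.
#'
#' @param dataset A [meta_dataset] carrying the moderators the
#'   specification needs (`method`, `statistic`, `data_year`, `income`).
#' @param spec One of `"s0"` ... `"s6"`.
#' @param bias `"none"`, `"pet"` (adds `se`), or `"peese"` (adds `se2`).
#' @return A numeric matrix with a `"(Intercept)"` column, full column
#'   rank, plus attributes `spec`, `bias`, `centers` (means used for
#'   centering) and `moderator_means` (column means, used by
#'   [compute_ievsl()]).
#' @export
build_design <- function(dataset, spec = "s0",
                         bias = c("none", "pet", "peese")) {
  stopifnot(inherits(dataset, "meta_dataset"))
  bias <- match.arg(bias)
  if (!spec %in% paste0("s", 0:6)) stop("unknown specification: ", spec)
  n <- nrow(dataset)
  need <- switch(spec,
                 s0 = character(0),
                 s1 = c("method", "statistic"),
                 s2 = c("method", "statistic", "data_year"),
                 s3 = c("method", "statistic", "income"),
                 s4 = c("method", "statistic", "data_year", "income"),
                 s5 = c("method", "statistic", "data_year"),
                 s6 = c("method", "statistic", "income"))
  miss <- setdiff(need, names(dataset))
  if (length(miss) > 0)
    stop("specification ", spec, " needs missing moderator column(s): ",
         paste(miss, collapse = ", "))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  centers <- c()
  add <- function(X, col, name) {
    X <- cbind(X, col); colnames(X)[ncol(X)] <- name; X
  }
  if (spec != "s0") {
    sp <- as.numeric(!is.na(dataset$method) & dataset$method == "SP")
    med <- as.numeric(!is.na(dataset$statistic) &
                        dataset$statistic == "median")
    X <- add(X, sp, "SP")
    X <- add(X, med, "median")
    if (spec %in% c("s2", "s4", "s5")) {
      yc <- mean(dataset$data_year)
      X <- add(X, dataset$data_year - yc, "year")
      centers["year"] <- yc
    }
    if (spec %in% c("s3", "s4", "s6")) {
      ic <- mean(dataset$income)
      X <- add(X, dataset$income - ic, "income")
      centers["income"] <- ic
    }
    if (spec == "s5") X <- add(X, sp * (dataset$data_year - centers["year"]),
                               "SP:year")
    if (spec == "s6") X <- add(X, sp * (dataset$income - centers["income"]),
                               "SP:income")
  }
  if (bias == "pet") X <- add(X, dataset$se, "se")
  if (bias == "peese") X <- add(X, dataset$se^2, "se2")
  if (qr(X)$rank < ncol(X))
    stop("design matrix for ", spec, " is rank deficient")
  structure(X, spec = spec, bias = bias, centers = centers,
            moderator_means = colMeans(X))
}

# weighted least squares with per-observation weights w (diagonal WLS)
.wls <- function(X, y, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  drop(beta)
}

# CR0 cluster sandwich for WLS coefficients, small-sample factor I/(I-1)
.cluster_robust_vcov <- function(X, y, w, beta, ids) {
  e <- y - drop(X %*% beta)
  bread <- solve(t(X * w) %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(ids)) {
    rows <- which(ids == g)
    sg <- colSums(X[rows, , drop = FALSE] * (w[rows] * e[rows]))
    meat <- meat + sg %o% sg
  }
  I <- length(unique(ids))
  (I / (I - 1)) * bread %*% meat %*% bread
}

#' Fit the two-stage random-effects meta-regression by iterated WLS
#'
#' Starting from \eqn{\hat\beta = 0}, iterates the full estimator
#' sequence: with the current fitted values, re-estimate the within-group
#' variances (the fitted-value sample variance is subtracted from the
#' effect-size sample variance), the between-group variance from weighted
#' group residuals, and the weights \eqn{w_{ij} = g_{ij} h_i}; then update
#' \eqn{\hat\beta} by weighted least squares.  Repeats until
#' \eqn{\max|\Delta\hat\beta|} falls below `tol`, with step halving if the
#' update oscillates.  With a constant-only design the estimator collapses
#' to [fit_2sre()] exactly and no iteration is performed.
#'
#' @param dataset A [meta_dataset].
#' @param design A design matrix from [build_design()] (or any numeric
#'   matrix whose first column is a constant).
#' @param variant `"equal"` or `"free"`.
#' @param rho Assumed within-group sampling-error correlation.
#' @param tol Convergence tolerance on `max(abs(diff(beta)))`.
#' @param max_iter Maximum iterations before failure.
#' @return An object of class `tsre_metareg`: coefficients `beta`, robust
#'   variance `vcov` and SEs, `components`, per-observation `weights`,
#'   weighted `r2`, iteration trace, `converged` flag.
#' @export
fit_2sre_metareg <- function(dataset, design, variant = c("equal", "free"),
                             rho = 0.5, tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(dataset, "meta_dataset"))
  variant <- match.arg(variant)
  X <- unclass(design)
  if (nrow(X) != nrow(dataset)) stop("design/dataset row mismatch")
  if (nrow(X) <= ncol(X)) stop("more parameters than observations")
  idx <- .group_index(dataset)
  I <- length(idx)
  y <- dataset$y
  ids <- dataset$group_id

  if (ncol(X) == 1 && all(X[, 1] == 1)) {
    # stated collapse: constant-only meta-regression IS the meta-analysis
    fit <- fit_2sre(dataset, variant = variant, rho = rho, se = "none")
    w <- fit$weights$w
    beta <- stats::setNames(fit$estimate, colnames(X))
    V <- .cluster_robust_vcov(X, y, w, beta, ids)
    out <- list(beta = beta, vcov = V,
                robust_se = stats::setNames(sqrt(pmax(diag(V), 0)), names(beta)),
                components = fit$components, weights = fit$weights,
                r2 = .weighted_r2(X, y, w, beta),
                iterations = 0L, converged = TRUE, trace = NULL,
                design = design, dataset = dataset,
                variant = variant, rho = rho,
                method_label = paste0("2SRE-", variant, " metareg (",
                                      attr(design, "spec") %||% "custom", ")"))
    class(out) <- "tsre_metareg"
    return(out)
  }

  beta <- rep(0, ncol(X))
  trace <- matrix(NA_real_, 0, ncol(X))
  converged <- FALSE
  last_raw <- Inf
  lambda <- 1   # relaxation factor, shrunk under oscillation
  w <- NULL
  comp <- NULL
  for (it in seq_len(max_iter)) {
    fitted <- drop(X %*% beta)
    res <- .tsre_sigma_mu(dataset, idx, rho, variant, fitted = fitted)
    smu <- res$sigma_mu_sq
    # weighted group residuals for the between-group component
    gl <- vector("list", I); cond <- numeric(I); eta_hat <- numeric(I)
    for (i in seq_len(I)) {
      rows <- idx[[i]]
      g <- within_group_weights(smu[i], dataset$se[rows], rho)
      gl[[i]] <- g
      cond[i] <- as.numeric(t(g) %*%
                              .group_cov(smu[i], dataset$se[rows], rho) %*% g)
      eta_hat[i] <- sum(g * (y[rows] - fitted[rows]))
    }
    seta <- if (I >= 2) estimate_sigma_eta(eta_hat, cond)$value else 0
    vh <- group_variances_and_weights(seta, cond)
    w <- numeric(nrow(dataset))
    for (i in seq_len(I)) w[idx[[i]]] <- gl[[i]] * vh$h[i]
    beta_target <- .wls(X, y, w)
    step <- beta_target - beta
    raw <- max(abs(step))
    trace <- rbind(trace, beta_target)
    # the variance-component truncation makes the update map piecewise;
    # a cycle straddling a truncation boundary is resolved by shrinking
    # the relaxation factor, which drives beta to the boundary point
    if (raw >= 0.999 * last_raw) lambda <- lambda / 2
    applied <- lambda * step
    if (raw < tol || max(abs(applied)) < tol) {
      if (raw < tol) beta <- beta_target
      comp <- new_variance_components(
        sigma_eta_sq = seta, sigma_mu_sq = smu, rho = rho,
        variant = variant, singleton_fill = res$singleton_fill,
        diagnostics = list(sigma_mu_truncations = res$trunc_count,
                           boundary_cycle = lambda < 1,
                           fixed_point_residual = raw))
      converged <- TRUE
      break
    }
    beta <- beta + applied
    last_raw <- raw
  }
  if (!converged)
    stop("iterated WLS did not converge in ", max_iter,
         " iterations (last max|delta beta| = ",
         format(last_raw, digits = 4), ")")
  names(beta) <- colnames(X)
  V <- .cluster_robust_vcov(X, y, w, beta, ids)
  out <- list(beta = beta, vcov = V,
              robust_se = stats::setNames(sqrt(pmax(diag(V), 0)), names(beta)),
              components = comp,
              weights = data.frame(group_id = ids,
                                   row = seq_len(nrow(dataset)), w = w),
              r2 = .weighted_r2(X, y, w, beta),
              iterations = it, converged = converged, trace = trace,
              design = design, dataset = dataset,
              variant = variant, rho = rho,
              method_label = paste0("2SRE-", variant, " metareg (",
                                    attr(design, "spec") %||% "custom",
                                    if ((attr(design, "bias") %||% "none")
                                        != "none")
                                      paste0("+", attr(design, "bias"))
                                    else "", ")"))
  class(out) <- "tsre_metareg"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted R^2: share of weighted variance around the weighted mean of y
# explained by the fit (weights = the fitted 2SRE w_ij)
.weighted_r2 <- function(X, y, w, beta) {
  e <- y - drop(X %*% beta)
  ybar <- sum(w * y) / sum(w)
  1 - sum(w * e^2) / sum(w * (y - ybar)^2)
}

#' @export
print.tsre_metareg <- function(x, digits = 4, ...) {
  cat(x$method_label, if (x$converged)
    sprintf("(converged in %d iterations)\n", x$iterations)
    else "(NOT converged)\n")
  tab <- cbind(estimate = x$beta, robust_se = x$robust_se,
               t = x$beta / x$robust_se)
  print(round(tab, digits))
  cat(sprintf("sigma_mu (pooled/mean) = %s, sigma_eta = %s, R2 = %s\n",
              format(sqrt(mean(x$components$sigma_mu_sq)), digits = digits),
              format(sqrt(x$components$sigma_eta_sq), digits = digits),
              format(x$r2, digits = digits)))
  invisible(x)
}

#' Leave-one-out predictions for a meta-regression specification
#'
#' Refits the full iterated estimator with each unit withheld (weights and
#' variance components re-estimated every fold) and predicts the held-out
#' observations.
#'
#' @param dataset A [meta_dataset] (n >= 3).
#' @param design A design from [build_design()]; rebuilt per fold so
#'   centering uses only the retained observations.
#' @param variant,rho,tol,max_iter Passed to [fit_2sre_metareg()].
#' @param loo_unit `"observation"` (default) or `"group"`: what to hold
#'   out per fold.
#' @return Numeric vector of out-of-fold predictions, one per observation,
#'   with attribute `loo_unit`.
#' @export
loo_predictions <- function(dataset, design, variant = "equal", rho = 0.5,
                            tol = 1e-8, max_iter = 200,
                            loo_unit = c("observation", "group")) {
  stopifnot(inherits(dataset, "meta_dataset"))
  loo_unit <- match.arg(loo_unit)
  n <- nrow(dataset)
  if (n < 3) stop("leave-one-out requires at least 3 observations")
  spec <- attr(design, "spec") %||% "s0"
  bias <- attr(design, "bias") %||% "none"
  folds <- if (loo_unit == "observation") as.list(seq_len(n))
           else .group_index(dataset)
  pred <- rep(NA_real_, n)
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    keep <- setdiff(seq_len(n), hold)
    sub <- as.data.frame(dataset)[keep, , drop = FALSE]
    sub <- meta_dataset(sub, units = attr(dataset, "units"))
    fit <- tryCatch(
      fit_2sre_metareg(sub, build_design(sub, spec = spec, bias = bias),
                       variant = variant, rho = rho, tol = tol,
                       max_iter = max_iter),
      error = function(e) stop("leave-one-out refit failed on fold ", f,
                               ": ", conditionMessage(e)))
    # predict held-out rows on the fold's design scale (fold centering)
    Xh <- .design_rows(dataset, hold, fit$design)
    pred[hold] <- drop(Xh %*% fit$beta)
  }
  structure(pred, loo_unit = loo_unit)
}

# build the design rows for held-out observations using the centers of a
# fitted (training) design
.design_rows <- function(dataset, rows, design) {
  spec <- attr(design, "spec") %||% "s0"
  bias <- attr(design, "bias") %||% "none"
  centers <- attr(design, "centers")
  d <- dataset[rows, , drop = FALSE]
  X <- matrix(1, length(rows), 1, dimnames = list(NULL, "(Intercept)"))
  if (spec != "s0") {
    sp <- as.numeric(!is.na(d$method) & d$method == "SP")
    med <- as.numeric(!is.na(d$statistic) & d$statistic == "median")
    X <- cbind(X, SP = sp, median = med)
    if ("year" %in% names(centers))
      X <- cbind(X, year = d$data_year - centers["year"])
    if ("income" %in% names(centers))
      X <- cbind(X, income = d$income - centers["income"])
    if (spec == "s5")
      X <- cbind(X, "SP:year" = sp * (d$data_year - centers["year"]))
    if (spec == "s6")
      X <- cbind(X, "SP:income" = sp * (d$income - centers["income"]))
  }
  if (bias == "pet") X <- cbind(X, se = d$se)
  if (bias == "peese") X <- cbind(X, se2 = d$se^2)
  X[, colnames(design), drop = FALSE]
}

#' Leave-one-out cross-validated R-squared
#'
#' \eqn{RCV^2 = 1 - \sum r_{(n)}^2 / \sum (y - \bar y)^2} where each
#' \eqn{r_{(n)}} is an out-of-fold residual from a full refit with that
#' unit withheld.
#'
#' @inheritParams loo_predictions
#' @return The cross-validated R-squared (at most 1; can be negative).
#' @export
compute_rcv2 <- function(dataset, design, variant = "equal", rho = 0.5,
                         tol = 1e-8, max_iter = 200,
                         loo_unit = c("observation", "group")) {
  loo_unit <- match.arg(loo_unit)
  pred <- loo_predictions(dataset, design, variant = variant, rho = rho,
                          tol = tol, max_iter = max_iter,
                          loo_unit = loo_unit)
  y <- dataset$y
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Income elasticity of the synthesized effect
#'
#' The proportional change in the model-predicted effect per proportional
#' change in income, evaluated at the means of all moderators:
#' \eqn{(\partial\hat y/\partial \mathrm{income}) \times
#' \bar{\mathrm{income}} / \hat y(\bar x)}.  Interaction terms contribute
#' through the mean of the interacting indicator (e.g. the SP share).
#'
#' @param fit A `tsre_metareg` whose specification includes income.
#' @param dataset The [meta_dataset] it was fitted to.
#' @return The elasticity (dimensionless).
#' @export
compute_ievsl <- function(fit, dataset) {
  stopifnot(inherits(fit, "tsre_metareg"))
  beta <- fit$beta
  if (!"income" %in% names(beta))
    stop("specification does not include income; elasticity undefined")
  xbar <- attr(fit$design, "moderator_means")
  yhat <- sum(beta * xbar[names(beta)])
  dydinc <- beta[["income"]]
  if ("SP:income" %in% names(beta))
    dydinc <- dydinc + beta[["SP:income"]] * xbar[["SP"]]
  mean_income <- mean(dataset$income)
  as.numeric(dydinc * mean_income / yhat)
}
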