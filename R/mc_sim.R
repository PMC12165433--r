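#' Define a Monte Carlo simulation design
#'
#' One cell of the simulation experiment: a true effect of 10, `I` groups
#' each contributing a uniform-integer number of observations, a
#' group-level error \eqn{\eta_i \sim N(0, \sigma_\eta^2)}, per-group
#' within-group dispersions \eqn{\sigma_{\mu,i}} drawn uniformly from a
#' range (so the within-group variance is heterogeneous across groups),
#' per-observation standard errors drawn uniformly from 0.5-5.0, and
#' exchangeable within-group sampling-error correlation \eqn{\rho}.
#' The defaults are the low-variability cell of the evaluation grid
#' (I = 20, J in 1-5, \eqn{\sigma_\eta} = 1, \eqn{\sigma_\mu} in 0.5-1.0,
#' \eqn{\rho} = 0.5); the grid varies I over \{20, 60\}, J over
#' \{1-5, 1-15\}, \eqn{\sigma_\eta} over \{1, 3\}, \eqn{\sigma_\mu} over
#' \{0.5-1.0, 0.5-3.0\}, and \eqn{(\rho, \hat\rho)} over \{0, 0.5\}^2.
#'
#' @param true_effect True effect size (default 10).
#' @param n_groups Number of groups I (default 20).
#' @param J_range Integer range (min, max) of observations per group.
#' @param sigma_eta Between-group non-sampling SD.
#' @param sigma_mu_range Range of within-group non-sampling SDs.
#' @param se_range Range of sampling standard errors.
#' @param rho True within-group sampling-error correlation.
#' @param n_trials Default trial count for experiments using this design.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(true_effect = 10, n_groups = 20,
                              J_range = c(1, 5), sigma_eta = 1,
                              sigma_mu_range = c(0.5, 1.0),
                              se_range = c(0.5, 5.0), rho = 0.5,
                              n_trials = 2000) {
  stopifnot(n_groups >= 1, J_range[1] >= 1, J_range[2] >= J_range[1],
            sigma_eta >= 0, sigma_mu_range[2] >= sigma_mu_range[1],
            sigma_mu_range[1] >= 0, se_range[1] > 0,
            se_range[2] >= se_range[1], abs(rho) < 1)
  structure(list(true_effect = true_effect, n_groups = n_groups,
                 J_range = J_range, sigma_eta = sigma_eta,
                 sigma_mu_range = sigma_mu_range, se_range = se_range,
                 rho = rho, n_trials = n_trials),
            class = "simulation_design")
}

#' Generate one synthetic meta-dataset
#'
#' Draws a dataset from the three-component error model
#' \eqn{y_{ij} = Y + \eta_i + \mu_{ij} + \varepsilon_{ij}} under a
#' [simulation_design()].  Within a group the sampling errors are jointly
#' normal with SDs \eqn{se_{ij}} and exchangeable correlation \eqn{\rho}
#' (constructed from a shared group factor, which requires
#' \eqn{\rho \ge 0}; negative \eqn{\rho} uses a Cholesky draw and must
#' keep the correlation matrix positive definite).  All error
#' distributions are normal.
#'
#' @param design A [simulation_design()].
#' @param seed Optional integer seed for bit-reproducibility.
#' @return A [meta_dataset] with attribute `true_components` (list:
#'   `sigma_eta_sq`, per-group `sigma_mu_sq`, `rho`) for use by the
#'   known-components estimator variant.
#' @export
gen_meta_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(seed)) set.seed(seed)
  I <- design$n_groups
  rho <- design$rho
  # avoid sample()'s scalar expansion when the range is degenerate
  J <- design$J_range[1] +
    sample.int(design$J_range[2] - design$J_range[1] + 1L, I,
               replace = TRUE) - 1L
  sigma_mu <- stats::runif(I, design$sigma_mu_range[1],
                           design$sigma_mu_range[2])
  eta <- stats::rnorm(I, 0, design$sigma_eta)
  rows <- vector("list", I)
  for (i in seq_len(I)) {
    Ji <- J[i]
    se <- stats::runif(Ji, design$se_range[1], design$se_range[2])
    mu <- stats::rnorm(Ji, 0, sigma_mu[i])
    if (rho >= 0) {
      z0 <- stats::rnorm(1)
      eps <- se * (sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(Ji))
    } else {
      R <- matrix(rho, Ji, Ji); diag(R) <- 1
      ch <- tryCatch(chol(R), error = function(e)
        stop("correlation ", rho, " is infeasible for a group of size ",
             Ji))
      eps <- se * drop(crossprod(ch, stats::rnorm(Ji)))
    }
    rows[[i]] <- data.frame(
      group_id = sprintf("g%02d", i),
      y = design$true_effect + eta[i] + mu + eps,
      se = se)
  }
  out <- meta_dataset(do.call(rbind, rows), units = "simulated")
  attr(out, "true_components") <- list(
    sigma_eta_sq = design$sigma_eta^2,
    sigma_mu_sq = stats::setNames(sigma_mu^2, sprintf("g%02d", seq_len(I))),
    rho = rho)
  out
}

#' Run a Monte Carlo estimator-comparison experiment
#'
#' For each design cell, generates `n_trials` datasets and applies every
#' estimator to the same datasets (common random numbers), then
#' summarizes each estimator's mean estimate, bias, the standard
#' deviation of its estimates across trials (the estimator's empirical
#' standard error), its mean robust SE, and the normalized precision
#' \eqn{(\hat{se} - se_{\min})/se_{\min}} relative to the benchmark
#' estimator (by default one named `"2sre_true"`, whose normalized
#' precision is 0 by construction).
#'
#' @param designs A [simulation_design()] or list of them (optionally
#'   named).
#' @param estimators Named list of functions
#'   `(meta_dataset) -> meta_estimate`.  Estimators wanting the true
#'   variance components can read `attr(dataset, "true_components")`.
#' @param n_trials Trials per design; default taken from each design.
#' @param master_seed Integer seed; per-trial seeds are spawned from it so
#'   results are reproducible and datasets are shared across estimators.
#' @param benchmark Name of the estimator whose empirical SD defines
#'   `se_min` (default `"2sre_true"` when present).
#' @return A data frame of class `performance_table`: one row per
#'   (design, estimator) with columns `design`, `estimator`,
#'   `mean_estimate`, `bias`, `sd_estimate`, `mean_robust_se`,
#'   `norm_precision`, `n_trials`, `n_failed`.  The per-trial estimates
#'   are attached as attribute `draws`.
#' @export
run_experiment <- function(designs, estimators, n_trials = NULL,
                           master_seed = 1, benchmark = "2sre_true") {
  if (inherits(designs, "simulation_design")) designs <- list(designs)
  if (is.null(names(designs)) || any(names(designs) == ""))
    names(designs) <- paste0("design", seq_along(designs))
  stopifnot(length(names(estimators)) == length(estimators),
            all(nzchar(names(estimators))))
  set.seed(master_seed)
  out <- list()
  draws_all <- list()
  for (dn in names(designs)) {
    design <- designs[[dn]]
    nt <- if (is.null(n_trials)) design$n_trials else n_trials
    trial_seeds <- sample.int(.Machine$integer.max - 1, nt)
    est_mat <- matrix(NA_real_, nt, length(estimators),
                      dimnames = list(NULL, names(estimators)))
    se_mat <- est_mat
    for (t in seq_len(nt)) {
      d <- gen_meta_dataset(design, seed = trial_seeds[t])
      for (en in names(estimators)) {
        r <- tryCatch(suppressWarnings(estimators[[en]](d)),
                      error = function(e) NULL)
        if (!is.null(r)) {
          est_mat[t, en] <- r$estimate
          se_mat[t, en] <- if (is.null(r$se)) NA_real_ else r$se
        }
      }
    }
    sds <- apply(est_mat, 2, stats::sd, na.rm = TRUE)
    se_min <- if (benchmark %in% names(estimators)) sds[[benchmark]]
              else min(sds, na.rm = TRUE)
    for (en in names(estimators)) {
      ests <- est_mat[, en]
      out[[length(out) + 1]] <- data.frame(
        design = dn, estimator = en,
        mean_estimate = mean(ests, na.rm = TRUE),
        bias = mean(ests, na.rm = TRUE) - design$true_effect,
        sd_estimate = sds[[en]],
        mean_robust_se = mean(se_mat[, en], na.rm = TRUE),
        norm_precision = (sds[[en]] - se_min) / se_min,
        n_trials = nt, n_failed = sum(is.na(ests)))
    }
    draws_all[[dn]] <- est_mat
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "draws") <- draws_all
  class(res) <- c("performance_table", "data.frame")
  res
}

#' Standard estimator bundle for experiments
#'
#' The three estimator variants under an assumed correlation
#' \eqn{\hat\rho}, ready for [run_experiment()]: `2sre_true` (true
#' variance components read off the generated dataset), `2sre_free`, and
#' `2sre_equal`.
#'
#' @param rho_hat Assumed correlation passed to each fit.
#' @param robust Whether fits compute robust SEs (slower).
#' @return Named list of estimator functions.
#' @export
tsre_estimator_set <- function(rho_hat = 0.5, robust = FALSE) {
  se <- if (robust) "robust" else "none"
  list(
    "2sre_true" = function(d) {
      tc <- attr(d, "true_components")
      if (is.null(tc)) stop("dataset carries no true components")
      fit_2sre(d, variant = "true", rho = tc$rho, known_components = tc,
               se = se)
    },
    "2sre_free" = function(d) fit_2sre(d, variant = "free", rho = rho_hat,
                                       se = se),
    "2sre_equal" = function(d) fit_2sre(d, variant = "equal",
                                        rho = rho_hat, se = se))
}

#' Synthetic fixture shaped like the EPA VSL meta-dataset
#'
#' Generates a clearly synthetic dataset with the same shape as the
#' agency compilation used in the demonstration application: 46
#' observations from 9 hedonic-wage groups and 25 from 1
#' quasi-experimental group (all revealed preference, all means), plus 42
#' observations from 9 stated-preference groups (a mixture of means and
#' medians), with plausible data years, incomes, magnitudes and standard
#' errors.  For testing and examples only; it is not the real
#' application data.
#'
#' @param seed Integer seed.
#' @return A [meta_dataset] with `method`, `statistic`, `data_year`,
#'   `income` moderators; 113 rows, 19 groups.
#' @export
make_epa_like_fixture <- function(seed = 42) {
  set.seed(seed)
  hw_sizes <- c(2, 3, 3, 4, 5, 5, 6, 8, 10)     # 46 hedonic-wage obs
  qe_size <- 25                                  # one quasi-experimental
  sp_sizes <- c(2, 3, 4, 4, 5, 5, 6, 6, 7)       # 42 stated-preference
  mk_group <- function(gid, J, method, center_mean, center_sd,
                       med_share = 0) {
    eta <- stats::rnorm(1, 0, 2)
    year <- sample(1999:2019, 1)
    se <- stats::runif(J, 0.6, 4.5)
    stat <- rep("mean", J)
    if (med_share > 0 && J >= 2) {
      n_med <- rbinom(1, J - 1, med_share)
      if (n_med > 0) stat[seq_len(n_med)] <- "median"
    }
    y <- center_mean + eta + stats::rnorm(J, 0, center_sd) +
      se * stats::rnorm(J) * 0.6 - 1.5 * (stat == "median")
    data.frame(group_id = gid, y = pmax(y, 0.3), se = se,
               method = method, statistic = stat, data_year = year,
               income = round(46 + 0.9 * (year - 1999) +
                                stats::rnorm(1, 0, 2), 1))
  }
  groups <- c(
    lapply(seq_along(hw_sizes), function(i)
      mk_group(sprintf("hw%02d", i), hw_sizes[i], "RP", 10.5, 1.5)),
    list(mk_group("qe01", qe_size, "RP", 10, 1.5)),
    lapply(seq_along(sp_sizes), function(i)
      mk_group(sprintf("sp%02d", i), sp_sizes[i], "SP", 8.5, 1.5,
               med_share = 0.5)))
  meta_dataset(do.call(rbind, groups))
}
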