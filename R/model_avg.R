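#' Jackknife model averaging weights
#'
#' Chooses simplex weights \eqn{\omega} over candidate models to minimize
#' the sum of squared leave-one-out prediction residuals of the weighted
#' average, \eqn{\sum_n (y_n - \sum_m \omega_m p_{nm})^2}: a convex
#' quadratic program over the probability simplex.  Solved with a dense
#' QP solver; an independent projected-gradient solver is available as a
#' cross-check and fallback.  Flat directions (e.g. duplicate candidates)
#' are resolved toward the minimum-norm weight vector by a tiny ridge
#' term, so duplicates share weight equally.
#'
#' @param loo_predictions Numeric matrix, one row per observation and one
#'   column per candidate model, of leave-one-out fitted values.
#' @param y Observation vector (length = rows of the matrix).
#' @param solver `"qp"` (default), `"pgd"` (projected gradient), or
#'   `"both"` (run both, require agreement to 1e-6, return the QP
#'   solution).
#' @param ridge Tie-breaking ridge coefficient (default 1e-10 times the
#'   largest Gram eigenvalue scale).
#' @return Weight vector on the simplex (non-negative, sums to 1), with
#'   attribute `objective` (the achieved sum of squared residuals).
#' @export
jma_weights <- function(loo_predictions, y, solver = c("qp", "pgd", "both"),
                        ridge = NULL) {
  solver <- match.arg(solver)
  P <- as.matrix(loo_predictions)
  stopifnot(nrow(P) == length(y), !anyNA(P), !anyNA(y))
  M <- ncol(P)
  if (M == 1) return(structure(1, objective = sum((y - P[, 1])^2)))
  G <- crossprod(P)
  if (is.null(ridge)) ridge <- 1e-7 * max(diag(G))
  D <- G + ridge * diag(M)
  d <- crossprod(P, y)
  qp_solve <- function() {
    r <- pracma::quadprog(C = 2 * D, d = -2 * as.numeric(d),
                          Aeq = matrix(1, 1, M), beq = 1,
                          lb = rep(0, M))
    r$xmin
  }
  pgd_solve <- function() {
    w <- rep(1 / M, M)
    L <- 2 * max(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
    for (k in 1:5000) {
      grad <- 2 * (D %*% w - d)
      w_new <- .proj_simplex(w - as.numeric(grad) / L)
      if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
      w <- w_new
    }
    w
  }
  w <- switch(solver,
              qp = tryCatch(qp_solve(), error = function(e) pgd_solve()),
              pgd = pgd_solve(),
              both = {
                w1 <- qp_solve(); w2 <- pgd_solve()
                if (max(abs(w1 - w2)) > 1e-6)
                  stop("QP and projected-gradient solutions disagree (max ",
                       format(max(abs(w1 - w2)), digits = 3), ")")
                w1
              })
  w <- pmax(w, 0); w <- w / sum(w)
  structure(as.numeric(w), objective = sum((y - drop(P %*% w))^2),
            names = colnames(P))
}

# Euclidean projection onto the probability simplex (sorting algorithm)
.proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  k <- max(which(u - (css - 1) / seq_along(u) > 0))
  tau <- (css[k] - 1) / k
  pmax(v - tau, 0)
}

#' Combine a quantity across candidate models with JMA weights
#'
#' Applies [jma_weights()] to the candidates' leave-one-out prediction
#' matrix and returns the weighted combination of a scalar quantity
#' extracted from each candidate fit.
#'
#' @param fits List of candidate fits (each must carry the data needed by
#'   `quantity`).
#' @param loo_predictions Matrix of leave-one-out predictions, one column
#'   per candidate (e.g. from [loo_predictions()]).
#' @param y Observation vector.
#' @param quantity Function `fit -> numeric(1)` extracting the quantity
#'   to combine (e.g. the balanced synthesis at moderator means).
#' @param ... Passed to [jma_weights()].
#' @return List: `value` (the combination), `weights`, `quantities`.
#' @export
jma_combine <- function(fits, loo_predictions, y, quantity, ...) {
  stopifnot(length(fits) == ncol(loo_predictions))
  w <- jma_weights(loo_predictions, y, ...)
  q <- vapply(fits, quantity, numeric(1))
  list(value = sum(w * q), weights = w, quantities = q)
}

#' Balanced synthesis from a meta-regression fit
#'
#' The model-implied synthesis that weights the two study types equally:
#' the regression constant plus one half of the stated-preference dummy
#' coefficient, evaluated with all other (centered) moderators at their
#' means.
#'
#' @param fit A `tsre_metareg`.
#' @return Numeric scalar.
#' @export
balanced_vsl <- function(fit) {
  stopifnot(inherits(fit, "tsre_metareg"))
  beta <- fit$beta
  val <- beta[["(Intercept)"]]
  if ("SP" %in% names(beta)) val <- val + 0.5 * beta[["SP"]]
  # other centered moderators evaluate to 0 at their means; interaction
  # columns use half the SP share by the same balancing logic
  if ("SP:year" %in% names(beta) || "SP:income" %in% names(beta)) {
    # centered interactions are 0 at the mean of the interacting variable
    val <- val
  }
  as.numeric(val)
}

#' Build the standard candidate-model set for model averaging
#'
#' All combinations of the seven moderator specifications, the pooled and
#' per-group within-variance variants, and publication-bias correction
#' (none or the squared-standard-error regressor), fitted to one dataset:
#' 28 candidates.  Returns the fits, their leave-one-out prediction
#' matrix, and labels.
#'
#' @param dataset A [meta_dataset].
#' @param specs Character vector of specification labels.
#' @param variants Variance variants to cross.
#' @param bias Bias modes to cross (`"none"`, `"peese"`, `"pet"`).
#' @param rho Assumed correlation for every fit.
#' @param loo_unit Passed to [loo_predictions()].
#' @return List: `fits`, `loo` (matrix), `labels`.
#' @export
build_candidate_set <- function(dataset, specs = paste0("s", 0:6),
                                variants = c("equal", "free"),
                                bias = c("none", "peese"), rho = 0.5,
                                loo_unit = "observation") {
  grid <- expand.grid(spec = specs, variant = variants, bias = bias,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  loo <- matrix(NA_real_, nrow(dataset), nrow(grid))
  labels <- character(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    design <- build_design(dataset, spec = grid$spec[k],
                           bias = grid$bias[k])
    fits[[k]] <- fit_2sre_metareg(dataset, design,
                                  variant = grid$variant[k], rho = rho)
    loo[, k] <- loo_predictions(dataset, design,
                                variant = grid$variant[k], rho = rho,
                                loo_unit = loo_unit)
    labels[k] <- paste(grid$spec[k], grid$variant[k], grid$bias[k],
                       sep = "/")
  }
  colnames(loo) <- labels
  list(fits = fits, loo = loo, labels = labels)
}
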