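# small in-code fixtures shared across test files

# three singleton groups with equal standard errors: 2SRE weights are
# exactly equal, so hand arithmetic on unweighted means applies
singleton_dataset <- function(y = c(1, 2, 3), se = 1) {
  meta_dataset(data.frame(group_id = paste0("g", seq_along(y)),
                          y = y, se = se))
}

# unbalanced two-group toy used in several places
toy_dataset <- function() {
  meta_dataset(data.frame(group_id = c("A", "A", "B"),
                          y = c(9, 11, 10), se = c(1, 1, 2)))
}

# random grouped dataset for property checks
random_dataset <- function(I = 6, Jmax = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- sample(1:Jmax, I, replace = TRUE)
  meta_dataset(data.frame(
    group_id = rep(sprintf("g%02d", seq_len(I)), J),
    y = rnorm(sum(J), 10, 2),
    se = runif(sum(J), 0.5, 3)))
}

# exact within-group covariance used by the GLS oracle
oracle_cov <- function(sigma_mu_sq, se, rho) {
  S <- rho * (se %o% se)
  diag(S) <- sigma_mu_sq + se^2
  S
}

# GLS oracle: variance-minimizing convex weights by direct inversion
oracle_gls_weights <- function(sigma_mu_sq, se, rho) {
  g <- solve(oracle_cov(sigma_mu_sq, se, rho), rep(1, length(se)))
  g / sum(g)
}
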