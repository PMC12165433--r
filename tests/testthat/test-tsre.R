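test_that("within-group variance estimator matches hand arithmetic and truncates", {
  # sample variance 2 minus mean sampling variance 1
  expect_equal(estimate_sigma_mu_group(c(9, 11), c(1, 1), rho = 0)$value, 1)
  # correlated sampling errors add back the cross-term
  expect_equal(estimate_sigma_mu_group(c(9, 11), c(1, 1), rho = 0.5)$value,
               1.5)
  # zero dispersion: raw value negative, truncated with a flag
  r <- estimate_sigma_mu_group(c(10, 10, 10), c(1, 2, 1), rho = 0)
  expect_equal(r$value, 0)
  expect_true(r$truncated)
  expect_lt(r$raw, 0)
  expect_error(estimate_sigma_mu_group(9, 1), "singleton")
  expect_error(estimate_sigma_mu_group(c(9, 11), c(1, 1), rho = 1),
               "rho")
})

test_that("within-group variance estimator is unbiased under correlated sampling errors", {
  # moment oracle: E[sample variance] = sigma_mu^2 + mean(se^2)
  #   - (1/(J(J-1))) sum_{j!=k} rho se_j se_k  under multivariate normal
  set.seed(101)
  J <- 4; se <- c(0.5, 1, 2, 3); rho <- 0.5; sigma_mu <- 1.2
  Sig <- oracle_cov(sigma_mu^2, se, rho)
  ch <- chol(Sig)
  nrep <- 20000
  vals <- replicate(nrep, {
    z <- drop(crossprod(ch, rnorm(J)))
    estimate_sigma_mu_group(10 + z, se, rho)$raw
  })
  mc_se <- sd(vals) / sqrt(nrep)
  expect_lt(abs(mean(vals) - sigma_mu^2), 3 * mc_se)
})

test_that("variant resolution fills singletons on the sigma scale and pools by df", {
  # non-singleton sigma_mu of 1.0 and 3.0 (sd scale): singleton gets 2.0
  res <- resolve_sigma_mu(c(1, 9, NA), J = c(3L, 4L, 1L), variant = "free")
  expect_equal(unname(res$sigma_mu_sq[3]), 4)      # (mean of 1 and 3)^2
  expect_equal(unname(res$sigma_mu_sq[1:2]), c(1, 9))
  # equal variant is idempotent on homogeneous inputs
  res2 <- resolve_sigma_mu(c(1, 1, 1), J = c(2L, 3L, 4L),
                           variant = "equal")
  expect_equal(unname(res2$sigma_mu_sq), rep(1, 3))
  # pooled value is a convex combination: inside [min, max]
  res3 <- resolve_sigma_mu(c(0.5, 4, 2), J = c(2L, 5L, 3L),
                           variant = "equal")
  expect_true(all(res3$sigma_mu_sq >= 0.5 & res3$sigma_mu_sq <= 4))
  # and equals the df-weighted mean
  expect_equal(unname(res3$sigma_mu_sq[1]),
               (1 * 0.5 + 4 * 4 + 2 * 2) / 7)
  # all-singleton fallback: zero with a warning
  expect_warning(res4 <- resolve_sigma_mu(c(NA, NA), J = c(1L, 1L),
                                          variant = "free"),
                 "singleton")
  expect_equal(unname(res4$sigma_mu_sq), c(0, 0))
})

test_that("within-group weights equal the variance-minimizing GLS solution", {
  expect_equal(as.numeric(within_group_weights(2, 1.5, 0.3)), 1)
  # independent case: inverse-variance on (1, 4)
  expect_equal(as.numeric(within_group_weights(0, c(1, 2), 0)),
               c(0.8, 0.2))
  # direct 3x3 covariance-inversion oracle
  g <- within_group_weights(1, c(0.5, 1, 2), 0.5)
  expect_equal(as.numeric(g), oracle_gls_weights(1, c(0.5, 1, 2), 0.5),
               tolerance = 1e-10)
  # property: GLS equivalence over random groups, plus normalization
  set.seed(7)
  for (k in 1:500) {
    J <- sample(2:6, 1)
    smu2 <- runif(1, 0, 5)
    rho <- runif(1, -0.2, 0.9)
    se <- runif(J, 0.3, 5)
    g <- within_group_weights(smu2, se, rho)
    expect_equal(sum(g), 1, tolerance = 1e-10)
    expect_equal(as.numeric(g), oracle_gls_weights(smu2, se, rho),
                 tolerance = 1e-8)
  }
})

test_that("group estimates and between-group weights follow their closed forms", {
  expect_equal(group_estimate(1, 7), 7)
  expect_equal(group_estimate(c(0.5, 0.5), c(9, 11)), 10)
  expect_equal(group_estimate(c(0.8, 0.2), c(10, 20)), 12)
  expect_error(group_estimate(c(0.5, 0.5), 1), "mismatch")

  expect_equal(group_variances_and_weights(0, c(1, 1, 1))$h, rep(1 / 3, 3))
  expect_equal(group_variances_and_weights(0, c(1, 3))$h, c(0.75, 0.25))
  # v_i = sigma_eta^2 + g' Sigma g identity on a random instance
  set.seed(11)
  se <- runif(4, 0.5, 3)
  g <- within_group_weights(0.8, se, 0.4)
  cond <- as.numeric(t(g) %*% oracle_cov(0.8, se, 0.4) %*% g)
  vh <- group_variances_and_weights(1.7, cond)
  expect_equal(vh$v, 1.7 + cond, tolerance = 1e-10)
})

test_that("between-group variance estimator subtracts conditional variances and truncates", {
  expect_equal(estimate_sigma_eta(c(9, 11), c(0, 0))$value, 2)
  r <- estimate_sigma_eta(c(10, 10, 10), c(0.5, 0.5, 0.5))
  expect_equal(r$value, 0)
  expect_true(r$truncated)
  expect_error(estimate_sigma_eta(10, 1), "single group")
})

test_that("the full fit respects degenerate limits", {
  # single observation: the estimate is that observation with weight 1
  d1 <- meta_dataset(data.frame(group_id = "a", y = 7, se = 2))
  f1 <- fit_2sre(d1, variant = "true", rho = 0,
                 known_components = list(sigma_eta_sq = 0, sigma_mu_sq = 0))
  expect_equal(f1$estimate, 7)
  expect_equal(f1$weights$w, 1)

  # all-singleton, equal se, known null components: the simple mean
  d2 <- singleton_dataset(y = c(4, 8, 12), se = 2)
  f2 <- fit_2sre(d2, variant = "true", rho = 0,
                 known_components = list(sigma_eta_sq = 0, sigma_mu_sq = 0))
  expect_equal(f2$estimate, 8)
  expect_equal(f2$weights$w, rep(1 / 3, 3))

  # one group, sigma_mu = 0, rho = 0: fixed-effect inverse-variance
  d3 <- meta_dataset(data.frame(group_id = "a", y = c(10, 12),
                                se = c(1, 2)))
  f3 <- fit_2sre(d3, variant = "true", rho = 0,
                 known_components = list(sigma_eta_sq = 0, sigma_mu_sq = 0))
  expect_equal(f3$estimate, 10.4)

  # dominant between-group variance: group weights approach 1/I
  d4 <- random_dataset(I = 5, seed = 3)
  f4 <- fit_2sre(d4, variant = "true", rho = 0,
                 known_components = list(sigma_eta_sq = 1e8,
                                         sigma_mu_sq = 1))
  expect_equal(f4$diagnostics$group_weights, rep(0.2, 5),
               tolerance = 1e-6)
})

test_that("weights are normalized at all three levels and the estimate is their inner product", {
  set.seed(23)
  for (k in 1:20) {
    d <- random_dataset(I = sample(3:8, 1), seed = NULL)
    f <- fit_2sre(d, variant = sample(c("free", "equal"), 1),
                  rho = runif(1, 0, 0.8), se = "none")
    expect_equal(sum(f$weights$w), 1, tolerance = 1e-10)
    expect_equal(sum(f$diagnostics$group_weights), 1, tolerance = 1e-10)
    for (g in unique(d$group_id)) {
      wg <- f$weights$w[d$group_id == g]
      hg <- f$diagnostics$group_weights[match(g, unique(d$group_id))]
      expect_equal(sum(wg / hg), 1, tolerance = 1e-8)
    }
    expect_equal(f$estimate, sum(f$weights$w * d$y), tolerance = 1e-10)
  }
})

test_that("the estimate is invariant to row order and group relabeling", {
  d <- random_dataset(I = 6, seed = 31)
  f0 <- fit_2sre(d, se = "none")
  perm <- sample(nrow(d))
  dp <- as.data.frame(d)[perm, ]
  dp$group_id <- paste0("relabel_", dp$group_id)
  fp <- fit_2sre(meta_dataset(dp), se = "none")
  expect_equal(fp$estimate, f0$estimate, tolerance = 1e-12)
  expect_equal(fp$se, f0$se)
})

test_that("point estimates are unbiased across (rho, rho_hat) combinations", {
  # mis-specified correlation must not introduce bias
  nt <- 250
  for (rho_true in c(0, 0.5)) for (rho_hat in c(0, 0.5)) {
    des <- simulation_design(rho = rho_true)
    set.seed(17 + 100 * rho_true + 10 * rho_hat)
    seeds <- sample.int(2^31 - 2, nt)
    for (variant in c("equal", "free")) {
      ests <- vapply(seeds, function(s)
        fit_2sre(gen_meta_dataset(des, s), variant = variant,
                 rho = rho_hat, se = "none")$estimate, numeric(1))
      mc_se <- sd(ests) / sqrt(nt)
      expect_lt(abs(mean(ests) - 10), 3 * mc_se)
    }
  }
})

test_that("the cluster-robust standard error matches the hand-computed sandwich", {
  # all residuals zero
  d0 <- singleton_dataset(y = c(5, 5, 5), se = 1)
  f0 <- fit_2sre(d0, variant = "true", rho = 0,
                 known_components = list(sigma_eta_sq = 0, sigma_mu_sq = 0))
  expect_equal(robust_se(d0, f0), 0)
  # four singleton groups, equal weights: the textbook
  # heteroskedasticity-robust SE of a weighted mean,
  # sqrt(n/(n-1) * sum(w^2 (y - ybar)^2))
  y <- c(2, 4, 6, 12)
  d4 <- singleton_dataset(y = y, se = 1)
  f4 <- fit_2sre(d4, variant = "true", rho = 0,
                 known_components = list(sigma_eta_sq = 0, sigma_mu_sq = 0))
  expect_equal(f4$weights$w, rep(0.25, 4))
  hand <- sqrt(4 / 3 * sum(0.25^2 * (y - 6)^2))
  expect_equal(robust_se(d4, f4), hand, tolerance = 1e-12)
})

test_that("cluster bootstrap is deterministic under a seed and degenerates correctly", {
  d <- random_dataset(I = 6, seed = 41)
  b1 <- cluster_bootstrap_se(d, B = 60, seed = 9)
  b2 <- cluster_bootstrap_se(d, B = 60, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$se, b2$se)
  # identical effects: every resample returns the same estimate
  dc <- singleton_dataset(y = rep(8, 4), se = c(1, 2, 1, 2))
  b3 <- cluster_bootstrap_se(dc, B = 40, seed = 2)
  expect_equal(b3$se, 0)
})

test_that("the bootstrap SE tracks the sampling variability of the estimator", {
  des <- simulation_design()
  set.seed(55)
  nt <- 120
  seeds <- sample.int(2^31 - 2, nt)
  ests <- vapply(seeds, function(s)
    fit_2sre(gen_meta_dataset(des, s), se = "none")$estimate, numeric(1))
  mc_sd <- sd(ests)
  b <- cluster_bootstrap_se(gen_meta_dataset(des, seeds[1]), B = 300,
                            seed = 3)
  expect_lt(abs(b$se - mc_sd) / mc_sd, 0.5)
})
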