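test_that("unweighted estimators match hand arithmetic", {
  expect_equal(simple_mean(singleton_dataset(y = c(1, 2, 3)))$estimate, 2)
  d1 <- meta_dataset(data.frame(group_id = "a", y = 5, se = 1))
  expect_equal(simple_mean(d1)$estimate, 5)

  d <- meta_dataset(data.frame(group_id = c("a", "a", "b"),
                               y = c(1, 3, 5), se = 1))
  expect_equal(group_means(d)$estimate, 3.5)
  expect_equal(sum(group_means(d)$weights$w), 1, tolerance = 1e-12)
  # balanced panel: group means equals the simple mean
  db <- meta_dataset(data.frame(group_id = rep(c("a", "b"), each = 2),
                                y = c(1, 2, 3, 4), se = 1))
  expect_equal(group_means(db)$estimate, simple_mean(db)$estimate)
})

test_that("fixed-effect inverse-variance weighting follows 1/se^2", {
  d <- meta_dataset(data.frame(group_id = c("a", "b"), y = c(10, 12),
                               se = c(1, 2)))
  expect_equal(fe_ivw(d)$estimate, 10.4)
  # equal se reduces to the simple mean
  de <- singleton_dataset(y = c(3, 6, 9), se = 2)
  expect_equal(fe_ivw(de)$estimate, 6)
  # a vanishing se dominates
  dd <- meta_dataset(data.frame(group_id = c("a", "b"), y = c(10, 20),
                                se = c(1e-6, 1)))
  expect_equal(fe_ivw(dd)$estimate, 10, tolerance = 1e-6)
})

test_that("DerSimonian-Laird matches the hand-computed Q and an independent implementation", {
  d <- meta_dataset(data.frame(group_id = c("a", "b"), y = c(8, 12),
                               se = c(1, 1)))
  f <- dl_re(d)
  expect_equal(f$estimate, 10)
  expect_equal(f$diagnostics$tau_sq, 7)   # Q = 8, df = 1, C = 1
  # homogeneous data: tau^2 = 0, reduces to fixed-effect weighting
  dh <- singleton_dataset(y = c(10, 10.1, 9.9), se = 2)
  expect_equal(dl_re(dh)$diagnostics$tau_sq, 0)
  expect_equal(dl_re(dh)$estimate, fe_ivw(dh)$estimate)
  # multi-observation groups are redirected to the aggregator
  expect_error(dl_re(toy_dataset()), "mad_aggregate")
  # cross-check tau^2 and the estimate against metafor on random data
  skip_if_not_installed("metafor")
  set.seed(19)
  y <- rnorm(12, 10, 3); se <- runif(12, 0.5, 2)
  ds <- singleton_dataset(y = y, se = se)
  ours <- dl_re(ds)
  ref <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(ours$estimate, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$diagnostics$tau_sq, ref$tau2, tolerance = 1e-8)
})

test_that("the dependent-observation aggregator reproduces composite variances", {
  # singletons pass through unchanged
  ds <- singleton_dataset(y = c(1, 2), se = c(1, 2))
  expect_equal(mad_aggregate(ds, 0.5)$se, c(1, 2))
  # two observations, se 1, rho 0: composite se 1/sqrt(2)
  d2 <- meta_dataset(data.frame(group_id = c("a", "a"), y = c(9, 11),
                                se = 1))
  expect_equal(mad_aggregate(d2, 0)$se, 1 / sqrt(2))
  # perfect correlation keeps the full se
  expect_equal(mad_aggregate(d2, 1)$se, 1)
  expect_equal(mad_aggregate(d2, 0.5)$y, 10)
})

test_that("correlated- and hierarchical-effects working models behave as specified", {
  # homogeneous singleton data: both reduce to fixed-effect weighting
  dh <- singleton_dataset(y = c(10, 10.05, 9.95, 10), se = 1.5)
  expect_equal(corr_weights(dh, 0.5)$estimate, fe_ivw(dh)$estimate,
               tolerance = 1e-6)
  expect_equal(suppressWarnings(hier_weights(dh))$estimate,
               fe_ivw(dh)$estimate, tolerance = 1e-6)
  # equal se within a group: equal within-group weights under CORR
  d <- meta_dataset(data.frame(group_id = rep(c("a", "b"), c(3, 2)),
                               y = c(8, 9, 10, 11, 12),
                               se = c(2, 2, 2, 1, 1)))
  w <- corr_weights(d, 0.5)$weights$w
  expect_equal(w[1], w[2]); expect_equal(w[2], w[3])
  # hierarchical model with forced components equals the two-stage fit
  # with independent sampling errors and pooled within-variance
  d2 <- random_dataset(I = 6, seed = 47)
  fit0 <- fit_2sre(d2, variant = "equal", rho = 0)
  forced <- list(sigma_eta_sq = fit0$components$sigma_eta_sq,
                 sigma_mu_sq = fit0$components$sigma_mu_sq)
  expect_equal(hier_weights(d2, known_components = forced)$estimate,
               fit0$estimate, tolerance = 1e-6)
})

test_that("the multilevel REML estimator matches closed forms and stays unbiased", {
  # balanced singleton one-way model with known residual variance v:
  # REML sigma_eta^2 = max(0, sample variance of y - v)
  set.seed(29)
  y <- rnorm(30, 10, 2)
  ds <- singleton_dataset(y = y, se = 1)
  f <- reml_multilevel(ds, rho_hat = 0)
  expect_equal(f$diagnostics$sigma_eta_sq, max(0, var(y) - 1),
               tolerance = 1e-4)
  expect_equal(f$estimate, mean(y), tolerance = 1e-8)
  # true sigma_eta = 0: estimate pinned at the boundary
  y0 <- rnorm(40, 10, 0.2)
  ds0 <- singleton_dataset(y = y0, se = 1)
  expect_lt(reml_multilevel(ds0, rho_hat = 0)$diagnostics$sigma_eta_sq,
            0.05)
  # cross-check against an independent REML implementation with a
  # user-specified sampling covariance (correlated within groups)
  skip_if_not_installed("metafor")
  d <- random_dataset(I = 8, seed = 53)
  rho <- 0.4
  idx <- split(seq_len(nrow(d)), d$group_id)
  V <- matrix(0, nrow(d), nrow(d))
  for (r in idx) {
    V[r, r] <- rho * (d$se[r] %o% d$se[r])
    diag(V)[r] <- d$se[r]^2
  }
  ref <- metafor::rma.mv(yi = d$y, V = V, random = ~ 1 | group_id,
                         data = data.frame(group_id = d$group_id),
                         method = "REML")
  ours <- reml_multilevel(d, rho_hat = rho)
  expect_equal(ours$estimate, as.numeric(ref$beta), tolerance = 1e-4)
  expect_equal(ours$diagnostics$sigma_eta_sq, ref$sigma2,
               tolerance = 1e-3)
})

test_that("every estimator agrees on balanced homogeneous data and is order invariant", {
  # equal se, no heterogeneity: everything is the simple mean
  db <- meta_dataset(data.frame(group_id = rep(c("a", "b", "c"), each = 2),
                                y = c(9.9, 10.1, 10.05, 9.95, 10, 10),
                                se = 1))
  target <- simple_mean(db)$estimate
  for (fn in list(group_means, fe_ivw,
                  function(d) corr_weights(d, 0),
                  function(d) hier_weights(d),
                  function(d) reml_multilevel(d, 0),
                  function(d) suppressWarnings(fit_2sre(d, "equal",
                                                        rho = 0)))) {
    expect_equal(fn(db)$estimate, target, tolerance = 1e-6)
  }
  # permutation invariance for the weighted comparators
  d <- random_dataset(I = 5, seed = 61)
  perm <- sample(nrow(d))
  dp <- meta_dataset(as.data.frame(d)[perm, ])
  for (fn in list(function(x) corr_weights(x, 0.5),
                  function(x) reml_multilevel(x, 0.5))) {
    expect_equal(fn(dp)$estimate, fn(d)$estimate, tolerance = 1e-8)
  }
  # convex weights summing to one
  for (res in list(corr_weights(d, 0.5), reml_multilevel(d, 0.5),
                   group_means(d), fe_ivw(d))) {
    expect_equal(sum(res$weights$w), 1, tolerance = 1e-10)
  }
})
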