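test_that("Cohen's d and Hedges g match closed-form hand computations", {
  # IHC-style summary: 110 vs 47 tissue specimens
  e <- smd(group_summary(110, 6.83, 1.56, 47, 2.15, 1.46), "cohen")
  expect_equal(e$estimate, 3.0568, tolerance = 1e-4)
  expect_equal(e$ci_low, 2.5762, tolerance = 1e-4)
  expect_equal(e$ci_high, 3.5374, tolerance = 1e-4)

  expect_equal(smd(group_summary(10, 5, 1, 10, 5, 1))$estimate, 0)
  # J = 1 - 3/(4*18 - 1)
  h <- smd(group_summary(10, 1, 1, 10, 0, 1), "hedges")
  expect_equal(h$estimate, 1 - 3 / 71, tolerance = 1e-12)

  expect_error(smd(group_summary(5, 1, 0, 5, 0, 0)), "zero")
})

test_that("SMD is antisymmetric under group swap with unchanged variance", {
  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(3:40, 1); n0 <- sample(3:40, 1)
    m1 <- rnorm(1, 5); m0 <- rnorm(1, 5)
    s1 <- runif(1, 0.3, 2); s0 <- runif(1, 0.3, 2)
    a <- smd(group_summary(n1, m1, s1, n0, m0, s0))
    b <- smd(group_summary(n0, m0, s0, n1, m1, s1))
    expect_equal(a$estimate, -b$estimate)
    expect_equal(a$variance, b$variance)
  }
})

test_that("heterogeneity statistics follow the Q / I2 definitions", {
  same <- list(study_effect(1, 0.5), study_effect(1, 0.5), study_effect(1, 2))
  h0 <- heterogeneity(same)
  expect_equal(h0$Q, 0)
  expect_equal(h0$I2, 0)

  h <- heterogeneity(list(study_effect(0, 1), study_effect(2, 1)))
  expect_equal(h$Q, 2)
  expect_equal(h$df, 1L)
  expect_equal(h$I2, 0.5)

  set.seed(6)
  for (i in 1:20) {
    eff <- Map(study_effect, rnorm(5, 0, 2), runif(5, 0.2, 3))
    I2 <- heterogeneity(eff)$I2
    expect_gte(I2, 0); expect_lt(I2, 1)
  }
  expect_error(heterogeneity(list(study_effect(1, 1))), "two")
})

test_that("DerSimonian-Laird pooling matches hand computation and limits", {
  res <- pool(list(study_effect(0, 1), study_effect(2, 1)), "random")
  expect_equal(res$tau2, 1)
  expect_equal(res$pooled, 1)
  expect_equal(res$se, 1)

  # homogeneous studies: random reduces to fixed exactly
  eff <- list(study_effect(1.2, 0.4), study_effect(1.2, 0.7), study_effect(1.2, 0.3))
  expect_equal(pool(eff, "random")$pooled, pool(eff, "fixed")$pooled)
  expect_equal(pool(eff, "random")$tau2, 0)

  set.seed(7)
  for (i in 1:20) {
    eff <- Map(study_effect, rnorm(6, 1, 1), runif(6, 0.2, 2))
    est <- vapply(eff, `[[`, numeric(1), "estimate")
    for (m in c("fixed", "random")) {
      p <- pool(eff, m)$pooled
      expect_gte(p, min(est)); expect_lte(p, max(est))
    }
  }
})

test_that("pooling agrees with metafor's DL and FE estimators", {
  skip_if_not_installed("metafor")
  set.seed(8)
  for (i in 1:10) {
    k <- sample(4:12, 1)
    yi <- rnorm(k, 1, 1); vi <- runif(k, 0.1, 2)
    eff <- Map(study_effect, yi, vi)
    mine <- pool(eff, "random")
    ref <- metafor::rma(yi = yi, vi = vi, method = "DL")
    expect_equal(mine$pooled, as.numeric(ref$b), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(mine$Q, ref$QE, tolerance = 1e-10)

    fixed <- pool(eff, "fixed")
    reff <- metafor::rma(yi = yi, vi = vi, method = "FE")
    expect_equal(fixed$pooled, as.numeric(reff$b), tolerance = 1e-10)
    expect_equal(fixed$se, reff$se, tolerance = 1e-10)
  }
})

test_that("the auto model follows the I2 > 50% or p < 0.05 rule", {
  hom <- Map(study_effect, rep(1, 4), rep(1, 4))
  expect_equal(pool(hom, "auto")$model, "fixed")
  het <- Map(study_effect, c(-2, 0, 2, 6), rep(0.2, 4))
  expect_equal(pool(het, "auto")$model, "random")
})

test_that("subgroup pooling handles singleton subgroups as their own effect", {
  eff <- Map(study_effect, c(1, 1.5, 0.8, 3), c(0.2, 0.3, 0.25, 0.4),
             c("a", "b", "c", "ihc"))
  sub <- subgroup_pool(eff, c("mRNA", "mRNA", "mRNA", "IHC"))
  expect_named(sub$subgroups, c("mRNA", "IHC"))
  expect_equal(sub$subgroups$IHC$pooled, 3)
  expect_equal(sub$subgroups$IHC$ci_low, eff[[4]]$ci_low)
  expect_equal(sub$subgroups$IHC$model, "single")
  # all one label reduces to plain pooling
  all_one <- subgroup_pool(eff, rep("x", 4))
  expect_equal(all_one$subgroups$x$pooled, pool(eff, "auto")$pooled)
})

test_that("leave-one-out produces k results and tracks outlier removal", {
  same <- Map(study_effect, rep(2, 3), rep(0.5, 3), c("a", "b", "c"))
  loo <- leave_one_out(same)
  expect_length(loo, 3)
  expect_equal(vapply(loo, `[[`, numeric(1), "pooled"), c(a = 2, b = 2, c = 2))

  eff <- Map(study_effect, c(1, 1.1, 0.9, 8), rep(0.3, 4), c("a", "b", "c", "out"))
  loo <- leave_one_out(eff, "fixed")
  full <- pool(eff, "fixed")$pooled
  expect_lt(loo$out$pooled, full)                  # dropping the outlier moves down
  expect_equal(loo$out$pooled, 1, tolerance = 0.01)
  expect_error(leave_one_out(same[1:2]), "three")
})

test_that("Begg's test matches the hand-computed concordant case", {
  # deviates perfectly concordant with variances, k = 4, no ties:
  # P - Q = 6, z = (6 - 1)/sqrt(4*3*13/18)
  eff <- Map(study_effect, c(0, 0.5, 1, 1.5), c(1, 2, 3, 4))
  b <- beggs_test(eff)
  expect_equal(b$P, 6L); expect_equal(b$Q, 0L)
  expect_equal(b$z, 5 / sqrt(4 * 3 * 13 / 18), tolerance = 1e-12)
  expect_equal(b$p, 2 * pnorm(-b$z))

  # reversing the variance order flips the sign of tau
  b2 <- beggs_test(Map(study_effect, c(0, 0.5, 1, 1.5), c(4, 3, 2, 1)))
  expect_equal(b2$tau, -b$tau)
  expect_error(beggs_test(eff[1:2]), "three")
})

test_that("Fisher-z pooling of correlations is exact for closed-form cases", {
  one <- pool_correlations(0.5, 30)
  expect_equal(one$pooled, 0.5, tolerance = 1e-12)
  expect_equal(one$ci_low, tanh(atanh(0.5) - qnorm(0.975) / sqrt(27)), tolerance = 1e-12)
  expect_equal(one$ci_high, tanh(atanh(0.5) + qnorm(0.975) / sqrt(27)), tolerance = 1e-12)

  two <- pool_correlations(c(0.5, 0.5), c(40, 40))
  expect_equal(two$pooled, 0.5, tolerance = 1e-12)
  expect_equal(pool_correlations(c(0, 0, 0), c(10, 20, 30))$pooled, 0)
  # round trip of the transform across the range
  r <- seq(-0.99, 0.99, by = 0.11)
  expect_equal(tanh(atanh(r)), r, tolerance = 1e-12)

  expect_error(pool_correlations(1, 10), "\\|r\\|")
  expect_error(pool_correlations(0.5, 3), "n >= 4")
})

test_that("Fisher-z pooling agrees with metafor on the z scale", {
  skip_if_not_installed("metafor")
  set.seed(9)
  r <- runif(6, -0.3, 0.8); n <- sample(10:80, 6)
  mine <- pool_correlations(r, n, model = "random")
  es <- metafor::escalc(measure = "ZCOR", ri = r, ni = n)
  ref <- metafor::rma(yi = es$yi, vi = es$vi, method = "DL")
  expect_equal(mine$pooled, tanh(as.numeric(ref$b)), tolerance = 1e-10)
  expect_equal(mine$ci_low, tanh(ref$ci.lb), tolerance = 1e-8)
})
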