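test_that("t statistics from summaries match hand-computed and t.test values", {
  # pooled-variance t on a merged microarray cohort summary
  st <- two_sample_t(group_summary(58, 8.30, 1.12, 17, 6.50, 1.51), "student")
  expect_equal(st$t, 5.366, tolerance = 1e-3)
  expect_equal(st$df, 73)

  # Welch on the IHC group summary
  we <- two_sample_t(group_summary(110, 6.83, 1.56, 47, 2.15, 1.46), "welch")
  expect_equal(abs(we$t), 18.01, tolerance = 1e-3)

  expect_equal(two_sample_t(group_summary(10, 4, 1, 10, 4, 1))$t, 0)

  # oracle: t.test on raw data reproduced from its own summary
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), 1, 1.5); y <- rnorm(sample(5:30, 1))
    gs <- group_summary(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
    ref_w <- t.test(x, y)
    mine_w <- two_sample_t(gs, "welch")
    expect_equal(mine_w$t, unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(mine_w$p, ref_w$p.value, tolerance = 1e-10)
    ref_s <- t.test(x, y, var.equal = TRUE)
    mine_s <- two_sample_t(gs, "student")
    expect_equal(mine_s$t, unname(ref_s$statistic), tolerance = 1e-10)
  }

  # student equals welch when variances and sizes agree
  gs <- group_summary(12, 5, 1.3, 12, 4, 1.3)
  expect_equal(two_sample_t(gs, "student")$t, two_sample_t(gs, "welch")$t)
})

test_that("ROC curves reproduce brute-force pairwise AUCs and pROC", {
  perfect <- roc_curve(c(5, 6, 1, 2), c("tumor", "tumor", "control", "control"))
  expect_equal(perfect$auc, 1)

  mixed <- roc_curve(c(3, 1, 2, 0), c("tumor", "tumor", "control", "control"))
  expect_equal(mixed$auc, 0.75)  # 3 of 4 pairs concordant

  # Mann-Whitney brute force with ties counted one half
  set.seed(11)
  for (i in 1:10) {
    v <- sample(0:8, 30, replace = TRUE)
    lab <- sample(rep(c("tumor", "control"), 15))
    pos <- v[lab == "tumor"]; neg <- v[lab == "control"]
    mw <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(roc_curve(v, lab)$auc, mw, tolerance = 1e-12)
  }

  skip_if_not_installed("pROC")
  set.seed(12)
  v <- rnorm(60); lab <- sample(rep(c("tumor", "control"), 30))
  ref <- pROC::roc(response = lab, predictor = v, levels = c("control", "tumor"),
                   direction = "<", quiet = TRUE)
  expect_equal(roc_curve(v, lab)$auc, as.numeric(ref$auc), tolerance = 1e-10)
})

test_that("random labels give chance-level AUC at large n", {
  set.seed(13)
  v <- rnorm(4000)
  lab <- sample(rep(c("tumor", "control"), 2000))
  expect_equal(roc_curve(v, lab)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_curve(v, rep("tumor", 4000)), "both")
})

test_that("Youden cutoffs match an exhaustive threshold scan", {
  v <- c(3, 1, 2, 0); lab <- c("tumor", "tumor", "control", "control")
  cut <- youden_cutoff(roc_curve(v, lab))
  # brute force over all distinct thresholds
  best <- -Inf; best_cut <- NULL
  for (ct in sort(unique(v))) {
    sens <- mean(v[lab == "tumor"] >= ct); spec <- mean(v[lab == "control"] < ct)
    j <- sens + spec - 1
    if (j > best || (j == best && ct < best_cut)) { best <- j; best_cut <- ct }
  }
  expect_equal(cut$j, best)
  expect_equal(cut$cutoff, best_cut)
  expect_equal(cut$j, 0.5)

  # perfectly separated: J = 1 at the lowest separating value
  sep <- youden_cutoff(roc_curve(c(5, 6, 1, 2), c("tumor", "tumor", "control", "control")))
  expect_equal(sep$j, 1)
  expect_equal(sep$cutoff, 5)

  # sens/spec at the cutoff are rank-invariant under monotone transforms
  set.seed(14)
  v <- rnorm(40); lab <- sample(rep(c("tumor", "control"), 20))
  a <- youden_cutoff(roc_curve(v, lab))
  b <- youden_cutoff(roc_curve(exp(v), lab))
  expect_equal(a$sens, b$sens); expect_equal(a$spec, b$spec)
})

test_that("2x2 derivation counts cells correctly", {
  v <- c(3, 1, 2, 0); lab <- c("tumor", "tumor", "control", "control")
  tab <- to_two_by_two(v, lab, 2)
  expect_equal(unlist(tab[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  expect_equal(tab$tp + tab$fn, 2L)  # tumor margin preserved

  sep <- to_two_by_two(c(5, 6, 1, 2), lab, 4)
  expect_equal(sep$fp + sep$fn, 0L)
  low <- to_two_by_two(v, lab, -1)
  expect_equal(low$fn, 0L); expect_equal(low$tn, 0L)
})

test_that("pooled accuracy behaves on homogeneous and zero-cell studies", {
  st <- list(tp = 9L, fn = 1L, fp = 1L, tn = 9L, cutoff = 0)
  same <- replicate(4, structure(st, class = "diagnostic_study"), simplify = FALSE)
  acc <- pool_accuracy(same)
  expect_equal(acc$sens$pooled, 0.9, tolerance = 1e-10)
  expect_equal(acc$spec$pooled, 0.9, tolerance = 1e-10)
  expect_equal(acc$lr_pos, 9, tolerance = 1e-9)

  # a zero-FP study gets the 0.5 correction and stays strictly below 1
  z <- structure(list(tp = 8L, fn = 2L, fp = 0L, tn = 10L, cutoff = 0),
                 class = "diagnostic_study")
  acc2 <- pool_accuracy(list(z, same[[1]]))
  expect_lt(acc2$spec$pooled, 1)
  # hand value for the corrected study's specificity logit: log(10.5/0.5)
  eff <- log(10.5 / 0.5)
  expect_lt(plogis(eff), 1)

  # pooled sens within the per-study (corrected) range
  set.seed(15)
  for (i in 1:10) {
    studies <- lapply(1:4, function(j) {
      to_two_by_two(rnorm(40, rep(c(1, 0), each = 20)),
                    rep(c("tumor", "control"), each = 20), 0.5)
    })
    acc3 <- pool_accuracy(studies)
    sens_i <- vapply(studies, function(s) {
      x <- c(s$tp, s$fn); if (any(c(s$tp, s$fn, s$fp, s$tn) == 0)) x <- x + 0.5
      x[1] / sum(x)
    }, numeric(1))
    expect_gte(acc3$sens$pooled, min(sens_i) - 1e-9)
    expect_lte(acc3$sens$pooled, max(sens_i) + 1e-9)
  }
  expect_error(pool_accuracy(same[1]), "two")
})

test_that("the summary ROC passes through a common operating point", {
  st <- list(tp = 90L, fn = 10L, fp = 10L, tn = 90L, cutoff = 0)
  same <- replicate(5, structure(st, class = "diagnostic_study"), simplify = FALSE)
  sr <- sroc(same)
  expect_equal(sr$b, 0)
  at01 <- sr$curve$sens[abs(sr$curve$fpr - 0.1) < 1e-9]
  expect_equal(at01, 0.9, tolerance = 1e-9)
  expect_gt(sr$auc, 0.9)
})

test_that("Fagan post-test probabilities follow Bayes on the odds scale", {
  f <- fagan(0.20, 0.95, 0.94)
  # hand computation: odds 0.25, LR- = 0.05/0.94; 0.25*LR-/(1 + 0.25*LR-)
  expect_equal(f$post_neg, 0.0125 / 0.94 / (1 + 0.0125 / 0.94), tolerance = 1e-12)
  expect_equal(f$post_pos, (0.25 * 0.95 / 0.06) / (1 + 0.25 * 0.95 / 0.06),
               tolerance = 1e-12)
  expect_equal(round(f$post_neg, 2), 0.01)

  # uninformative test: LR = 1 leaves the probability unchanged
  f2 <- fagan(0.3, 0.7, 0.3)
  expect_equal(f2$post_pos, 0.3, tolerance = 1e-12)

  f3 <- fagan(0.5, 0.8, 0.8)
  expect_equal(f3$lr_pos, 4)
  expect_equal(f3$post_pos, 0.8, tolerance = 1e-12)

  # monotone in LR+
  posts <- vapply(seq(0.5, 0.95, by = 0.05),
                  function(s) fagan(0.2, s, 0.9)$post_pos, numeric(1))
  expect_true(all(diff(posts) > 0))
  expect_error(fagan(0, 0.9, 0.9), "strictly")
  expect_error(fagan(0.2, 1, 0.9), "strictly")
})
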