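test_that("DE screening applies strict thresholds and recovers planted genes", {
  # planted cohort: 50 up at +2, 50 down at -2, 900 nulls, n = 20/20
  design <- data.frame(cohort_id = "c1", platform_id = "p1",
                       n_tumor = 20L, n_control = 20L)
  sim <- simulate_cohorts(simulation_spec(seed = 101, cohorts = design,
                                          n_genes = 1000, n_up = 50, n_down = 50,
                                          coexpr_size = 0, target_smd = 0))
  df <- de_screen(sim$cohorts[[1]])
  truth <- sim$truth$deg
  planted_hit <- sum(df$pass & df$gene %in% truth$gene)
  expect_gte(planted_hit, 90)
  nulls <- setdiff(df$gene, c(truth$gene, "BUB1B"))
  expect_lte(mean(df$pass[df$gene %in% nulls]), 0.05)
  # recovered directions match the planted signs
  hits <- merge(df[df$pass, ], truth, by = "gene")
  expect_true(all(hits$direction.x == hits$direction.y))

  # boundary: |log2FC| must strictly exceed the threshold
  expect_false(any(df$pass & abs(df$log2fc) <= 1))

  lin <- sim$cohorts[[1]]; lin$is_log_scale <- FALSE
  expect_error(de_screen(lin), "log2")
})

test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(16)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("co-expression screening finds latent-factor partners and excludes the target", {
  # true correlation 0.6: lambda^2/(lambda^2 + 1) = 0.6
  set.seed(17)
  lam <- sqrt(1.5); n <- 50
  f <- rnorm(n)
  mat <- rbind(TARGET = lam * f + rnorm(n),
               t(replicate(50, lam * f + rnorm(n))),
               NEG = -(lam * f) + rnorm(n, sd = 0.1))
  rownames(mat) <- c("TARGET", sprintf("CO%02d", 1:50), "NEG")
  colnames(mat) <- paste0("s", 1:n)
  co <- expression_cohort(mat, rep(c("tumor", "control"), n / 2), "cx",
                          is_log_scale = TRUE)
  res <- ceg_screen(co, "TARGET")
  expect_false("TARGET" %in% res$gene)
  expect_gte(mean(res$pass[grepl("^CO", res$gene)]), 0.95)
  expect_equal(res$direction[res$gene == "NEG"], "neg")
  expect_true(res$pass[res$gene == "NEG"])

  # exact negative of the target: r = -1
  mat2 <- rbind(TARGET = f, ANTI = -f, OTHER = rnorm(n))
  colnames(mat2) <- paste0("s", 1:n)
  co2 <- expression_cohort(mat2, rep(c("tumor", "control"), n / 2), "cx2",
                           is_log_scale = TRUE)
  res2 <- ceg_screen(co2, "TARGET")
  expect_equal(res2$r[res2$gene == "ANTI"], -1)
  expect_equal(res2$p[res2$gene == "ANTI"], 0)

  # constant genes are skipped with a warning
  mat3 <- rbind(TARGET = f, FLAT = rep(1, n), OK = rnorm(n))
  colnames(mat3) <- paste0("s", 1:n)
  co3 <- expression_cohort(mat3, rep(c("tumor", "control"), n / 2), "cx3",
                           is_log_scale = TRUE)
  expect_warning(res3 <- ceg_screen(co3, "TARGET"), "constant")
  expect_false("FLAT" %in% res3$gene)
})

test_that("vote counting requires direction-consistent support and matches a brute-force tally", {
  lists <- list(
    data.frame(gene = c("A", "B", "C"), direction = c("up", "up", "down")),
    data.frame(gene = c("A", "B"), direction = c("up", "down")),
    data.frame(gene = c("A", "B"), direction = c("up", "up")),
    data.frame(gene = c("A", "B"), direction = c("up", "down")),
    data.frame(gene = c("A", "C"), direction = c("up", "down")))
  votes <- vote_count(lists, 5)
  expect_equal(votes$gene, "A")          # 5 consistent votes
  expect_equal(votes$n_cohorts, 5L)
  # B: 3 up + 2 down -> neither direction reaches 5
  expect_false("B" %in% votes$gene)
  expect_error(vote_count(lists[1:3], 5), "min_repetition")

  # random 9-cohort fixture against an independent tally
  set.seed(18)
  rand_lists <- lapply(1:9, function(i) {
    g <- sample(LETTERS[1:12], sample(4:9, 1))
    data.frame(gene = g, direction = sample(c("up", "down"), length(g), TRUE))
  })
  votes2 <- vote_count(rand_lists, 3)
  brute <- table(unlist(lapply(rand_lists, function(df)
    paste(df$gene, df$direction))))
  for (i in seq_len(nrow(votes2))) {
    key <- paste(votes2$gene[i], votes2$direction[i])
    expect_equal(votes2$n_cohorts[i], unname(as.integer(brute[key])))
  }
  brute_pass <- sort(names(brute)[brute >= 3])
  expect_equal(sort(paste(votes2$gene, votes2$direction)), brute_pass)
  # permutation invariance in cohort order
  votes3 <- vote_count(rev(rand_lists), 3)
  expect_equal(votes2, votes3)
})

test_that("SMD confirmation pools per-cohort effects and signs match planted truth", {
  design <- default_cohort_design()[c(2, 7, 8, 9), ]
  sim <- simulate_cohorts(simulation_spec(seed = 102, cohorts = design,
                                          n_genes = 60, n_up = 10, n_down = 10,
                                          coexpr_size = 5, target_smd = 2))
  conf <- smd_confirm(sim$cohorts, c(sim$truth$deg$gene, "G0055"))
  truth <- sim$truth$deg
  merged <- merge(conf, truth, by = "gene")
  expect_true(all(merged$confirmed == merged$direction))
  expect_true(all(sign(merged$pooled) == sign(merged$delta)))

  # genes observed in fewer than two cohorts are skipped with a warning
  one <- sim$cohorts[[1]]
  small <- expression_cohort(one$matrix[1:5, , drop = FALSE], one$group,
                             "tiny", is_log_scale = TRUE)
  expect_warning(conf2 <- smd_confirm(list(small, sim$cohorts[[2]]), c("G0055", "G0001")),
                 "skipped")

  # null genes rarely confirmed across seeded replicates (full 9-cohort design)
  confirmed_null <- vapply(1:40, function(i) {
    s <- simulate_cohorts(simulation_spec(seed = 200 + i, n_genes = 10,
                                          n_up = 1, n_down = 1,
                                          coexpr_size = 1, target_smd = 0))
    cf <- smd_confirm(s$cohorts, "G0008")  # a null gene
    cf$confirmed != "none"
  }, logical(1))
  expect_lte(mean(confirmed_null), 0.10)
})

test_that("gene-set intersections follow plain set algebra and drop the target", {
  s <- intersect_sets(up = c("X", "Y", "T1"), down = c("D"),
                      pos_r = c("Y", "Z", "T1"), neg_r = c("Q"),
                      target = "T1")
  expect_equal(s$A, "Y")
  expect_equal(s$B, character(0))
  expect_warning(intersect_sets("A", "B", "C", "D"), "empty")

  # brute-force oracle on random fixtures
  set.seed(19)
  for (i in 1:10) {
    up <- sample(LETTERS, 8); down <- sample(LETTERS, 8)
    pos <- sample(LETTERS, 8); neg <- sample(LETTERS, 8)
    got <- suppressWarnings(intersect_sets(up, down, pos, neg))
    expect_equal(got$A, sort(unique(up[up %in% pos])))
    expect_equal(got$B, sort(unique(down[down %in% neg])))
  }
})
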