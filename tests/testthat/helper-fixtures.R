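# Small in-code fixtures shared across test files.

# cohort from an explicit matrix; defaults give 3 genes x 4 samples
make_cohort <- function(mat = NULL, group = c("tumor", "tumor", "control", "control"),
                        id = "test", platform = "plat", log_scale = TRUE, ...) {
  if (is.null(mat)) {
    mat <- matrix(c(5, 6, 3, 4,
                    2, 2, 2, 2,
                    1, 0, 7, 8), nrow = 3, byrow = TRUE,
                  dimnames = list(c("TP53", "GAPDH", "BRCA1"),
                                  paste0("s", seq_along(group))))
  }
  expression_cohort(mat, group, id, platform, is_log_scale = log_scale, ...)
}

# random cohort with n1 tumors, n0 controls and a planted shift on gene 1
random_cohort <- function(seed, n_genes = 20, n1 = 10, n0 = 10, delta1 = 0,
                          id = "rand", platform = "plat") {
  set.seed(seed)
  n <- n1 + n0
  mat <- matrix(rnorm(n_genes * n, 6), n_genes, n,
                dimnames = list(sprintf("GENE%03d", seq_len(n_genes)),
                                sprintf("%s_s%02d", id, seq_len(n))))
  group <- c(rep("tumor", n1), rep("control", n0))
  mat[1, group == "tumor"] <- mat[1, group == "tumor"] + delta1
  expression_cohort(mat, group, id, platform, is_log_scale = TRUE)
}

write_expression_fixture <- function(dir, genes, values, samples, groups) {
  mat_path <- file.path(dir, "expr.tsv")
  sheet_path <- file.path(dir, "samples.tsv")
  df <- data.frame(gene = genes, values, check.names = FALSE)
  colnames(df)[-1] <- samples
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = samples, group = groups),
              sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mat_path, sheet = sheet_path)
}

# exact null pmf of Kendall's D = P - Q for k untied items, via the
# inversion-count recurrence (number of permutations with q inversions)
kendall_D_pmf <- function(k) {
  f <- 1
  for (n in 2:k) f <- convolve(f, rev(rep(1, n)), type = "open")
  q <- seq_along(f) - 1
  data.frame(D = k * (k - 1) / 2 - 2 * q, prob = f / sum(f))
}
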