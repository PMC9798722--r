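.row_group_stats <- function(mat, idx) {
  n <- length(idx)
  sub <- mat[, idx, drop = FALSE]
  m <- rowMeans(sub)
  s2 <- if (n >= 2L) rowSums((sub - m)^2) / (n - 1) else rep(NA_real_, nrow(mat))
  list(n = n, mean = m, var = s2)
}

#' Per-cohort differential-expression screen
#'
#' For every gene: log2 fold change = tumor mean minus control mean (the
#' cohort must already be on the log2 scale), a per-gene Welch t p-value,
#' and Benjamini-Hochberg adjustment across all genes of the cohort. A gene
#' passes when `|log2FC| > lfc_threshold` and adjusted p `< alpha` (strict
#' inequalities). Genes whose variance vanishes in both groups get `p = NA`
#' and never pass.
#'
#' @param cohort A log-scale [expression_cohort()] with >= 2 samples per
#'   group.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return data.frame `gene`, `log2fc`, `t`, `p`, `padj`, `direction`
#'   (`"up"`/`"down"`), `pass`.
#' @export
de_screen <- function(cohort, lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!cohort$is_log_scale)
    stop(sprintf("cohort '%s' is not flagged log2 scale; refusing to screen", cohort$cohort_id))
  i1 <- which(cohort$group == "tumor")
  i0 <- which(cohort$group == "control")
  if (length(i1) < 2L || length(i0) < 2L)
    stop(sprintf("cohort '%s' needs >= 2 samples per group", cohort$cohort_id))
  g1 <- .row_group_stats(cohort$matrix, i1)
  g0 <- .row_group_stats(cohort$matrix, i0)
  lfc <- g1$mean - g0$mean
  a <- g1$var / g1$n; b <- g0$var / g0$n
  se <- sqrt(a + b)
  t <- ifelse(se > 0, lfc / se, NA_real_)
  df <- (a + b)^2 / (a^2 / (g1$n - 1) + b^2 / (g0$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  padj <- bh_adjust(ifelse(is.na(p), 1, p))
  padj[is.na(p)] <- NA_real_
  pass <- !is.na(p) & abs(lfc) > lfc_threshold & padj < alpha
  data.frame(gene = rownames(cohort$matrix), log2fc = lfc, t = t, p = p,
             padj = padj,
             direction = ifelse(lfc >= 0, "up", "down"),
             pass = pass, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`; input
#' order is preserved.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-cohort co-expression screen against a target gene
#'
#' Pearson correlation of each gene with the target across all samples
#' (tumor and control pooled), p-value from
#' `t = r sqrt((n-2) / (1-r^2))` on `n-2` df. A gene passes when
#' `|r| >= r_threshold` and `p < alpha`. The target itself is excluded;
#' constant genes are skipped with a warning.
#'
#' @param cohort An [expression_cohort()] with >= 4 samples.
#' @param target Target gene symbol.
#' @param r_threshold Absolute correlation threshold (default 0.3, non-strict).
#' @param alpha p-value threshold (default 0.05, strict).
#' @return data.frame `gene`, `r`, `p`, `direction` (`"pos"`/`"neg"`),
#'   `pass`.
#' @export
ceg_screen <- function(cohort, target, r_threshold = 0.3, alpha = 0.05) {
  stopifnot(inherits(cohort, "expression_cohort"))
  target <- toupper(target)
  if (!target %in% rownames(cohort$matrix))
    stop(sprintf("target gene '%s' not present in cohort '%s'", target, cohort$cohort_id))
  n <- ncol(cohort$matrix)
  if (n < 4L) stop("co-expression screening needs >= 4 samples")
  y <- cohort$matrix[target, ]
  if (stats::sd(y) == 0)
    stop(sprintf("target gene '%s' is constant in cohort '%s'", target, cohort$cohort_id))
  mat <- cohort$matrix[setdiff(rownames(cohort$matrix), target), , drop = FALSE]
  sds <- sqrt(rowSums((mat - rowMeans(mat))^2) / (n - 1))
  const <- sds == 0
  if (any(const))
    warning(sprintf("%d constant gene(s) skipped in cohort '%s'",
                    sum(const), cohort$cohort_id))
  mat <- mat[!const, , drop = FALSE]
  r <- as.numeric(stats::cor(t(mat), y))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), n - 2)
  p[abs(r) >= 1] <- 0
  data.frame(gene = rownames(mat), r = r, p = p,
             direction = ifelse(r >= 0, "pos", "neg"),
             pass = abs(r) >= r_threshold & p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-cohort vote counting
#'
#' A gene is retained when it passes, with the same direction, in at least
#' `min_repetition` cohorts. Conflicting directions are tallied separately
#' and never add up.
#'
#' @param cohort_lists List (one element per cohort) of data.frames with
#'   columns `gene` and `direction` holding that cohort's passing genes
#'   (e.g. filtered [de_screen()]/[ceg_screen()] output).
#' @param min_repetition Minimum number of supporting cohorts (default 5).
#' @return data.frame `gene`, `direction`, `n_cohorts`, sorted by
#'   decreasing support, containing only genes that meet the threshold.
#' @export
vote_count <- function(cohort_lists, min_repetition = 5L) {
  if (length(cohort_lists) < min_repetition)
    stop(sprintf("only %d cohort lists supplied but min_repetition = %d",
                 length(cohort_lists), min_repetition))
  per <- lapply(cohort_lists, function(df) {
    if (!all(c("gene", "direction") %in% names(df)))
      stop("each cohort list needs 'gene' and 'direction' columns")
    unique(df[, c("gene", "direction")])
  })
  all_ <- do.call(rbind, per)
  if (is.null(all_) || !nrow(all_))
    return(data.frame(gene = character(), direction = character(),
                      n_cohorts = integer(), stringsAsFactors = FALSE))
  tab <- stats::aggregate(list(n_cohorts = rep(1L, nrow(all_))),
                          by = all_[, c("gene", "direction")], FUN = sum)
  tab <- tab[tab$n_cohorts >= min_repetition, , drop = FALSE]
  tab <- tab[order(-tab$n_cohorts, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Confirm candidate genes by pooled SMD confidence intervals
#'
#' For each gene, the per-cohort tumor-vs-control SMDs are pooled
#' (model auto). A gene is confirmed up-regulated when the pooled 95% CI
#' lies entirely above zero, and down-regulated when entirely below. Genes
#' measurable in fewer than two cohorts are skipped with a warning.
#'
#' @param cohorts List of [expression_cohort()]s.
#' @param genes Genes to confirm; default all genes present in >= 2
#'   cohorts.
#' @param correction SMD flavor passed to [smd()].
#' @return data.frame `gene`, `pooled`, `ci_low`, `ci_high`, `k`,
#'   `confirmed` (`"up"`, `"down"` or `"none"`).
#' @export
smd_confirm <- function(cohorts, genes = NULL, correction = "cohen") {
  gene_tab <- table(unlist(lapply(cohorts, function(co) rownames(co$matrix))))
  if (is.null(genes)) genes <- names(gene_tab)[gene_tab >= 2L]
  genes <- toupper(genes)
  skipped <- genes[!(genes %in% names(gene_tab)) | gene_tab[genes] < 2L]
  if (length(skipped)) {
    warning(sprintf("%d gene(s) present in < 2 cohorts skipped", length(skipped)))
    genes <- setdiff(genes, skipped)
  }
  rows <- lapply(genes, function(g) {
    effects <- list()
    for (co in cohorts) {
      if (!g %in% rownames(co$matrix)) next
      gs <- summarize_group(co, g)
      if (!gs$usable || (gs$sd1 == 0 && gs$sd0 == 0)) next
      effects[[length(effects) + 1L]] <- smd(gs, correction)
    }
    if (length(effects) < 2L) return(NULL)
    res <- pool(effects, "auto")
    data.frame(gene = g, pooled = res$pooled, ci_low = res$ci_low,
               ci_high = res$ci_high, k = res$k,
               confirmed = if (res$ci_low > 0) "up"
                           else if (res$ci_high < 0) "down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), pooled = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      k = integer(), confirmed = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Intersect confirmed DEGs with co-expression votes (gene sets A and B)
#'
#' Set A = confirmed up-regulated genes that are positively correlated with
#' the target; set B = confirmed down-regulated genes negatively correlated
#' with it. The target gene is excluded from both.
#'
#' @param up,down Character vectors of confirmed up/down genes.
#' @param pos_r,neg_r Character vectors of positively/negatively correlated
#'   genes.
#' @param target Target gene symbol to drop from both sets (optional).
#' @return List `A`, `B` (sorted character vectors).
#' @export
intersect_sets <- function(up, down, pos_r, neg_r, target = NULL) {
  A <- sort(intersect(toupper(up), toupper(pos_r)))
  B <- sort(intersect(toupper(down), toupper(neg_r)))
  if (!is.null(target)) {
    A <- setdiff(A, toupper(target))
    B <- setdiff(B, toupper(target))
  }
  if (!length(A) && !length(B))
    warning("both intersections are empty")
  list(A = A, B = B)
}
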