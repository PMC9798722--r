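#' Convert FPKM to TPM
#'
#' TPM renormalizes each sample so abundances sum to one million:
#' `tpm_i = fpkm_i / sum_j fpkm_j * 1e6`, applied column-wise.
#'
#' @param x Nonnegative numeric vector (one sample) or matrix
#'   (genes x samples).
#' @return Same shape as `x`, each sample summing to 1e6.
#' @export
fpkm_to_tpm <- function(x) {
  if (is.matrix(x)) {
    tot <- colSums(x)
    zero <- which(tot <= 0)
    if (length(zero))
      stop(sprintf("all-zero sample(s): %s",
                   paste(colnames(x)[zero] %||% zero, collapse = ", ")))
    return(sweep(x, 2L, tot, "/") * 1e6)
  }
  if (any(x < 0)) stop("FPKM values must be nonnegative")
  tot <- sum(x)
  if (tot <= 0) stop("all-zero sample: no positive FPKM value")
  x / tot * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log2-transform a cohort
#'
#' Applies `log2(x + 1)` and flags the cohort as log scale. A cohort already
#' on the log scale is returned unchanged with a warning, which makes the
#' transform idempotent.
#'
#' @param cohort An [expression_cohort()].
#' @return The transformed cohort with `is_log_scale = TRUE`.
#' @export
log2_transform <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (cohort$is_log_scale) {
    warning(sprintf("cohort '%s' is already log2 scale; nothing done", cohort$cohort_id))
    return(cohort)
  }
  if (any(cohort$matrix < 0))
    stop("negative values: cannot log2-transform (is the cohort already log scale?)")
  cohort$matrix <- log2(cohort$matrix + 1)
  cohort$is_log_scale <- TRUE
  cohort
}

#' Merge cohorts that share a platform
#'
#' Column-concatenates the cohorts restricted to their common genes. The
#' source cohort id of every sample is kept as its batch label so that
#' [batch_center()] (or a per-batch meta-analysis) can still see the
#' original structure.
#'
#' @param cohorts List of [expression_cohort()]s with identical
#'   `platform_id`.
#' @param merged_id Id for the merged cohort; defaults to the platform id.
#' @return A merged [expression_cohort()].
#' @export
merge_same_platform <- function(cohorts, merged_id = NULL) {
  stopifnot(length(cohorts) >= 2L)
  platforms <- vapply(cohorts, function(co) co$platform_id, character(1))
  if (length(unique(platforms)) != 1L)
    stop(sprintf("cohorts are not on one platform: %s",
                 paste(unique(platforms), collapse = ", ")))
  scales <- vapply(cohorts, function(co) co$is_log_scale, logical(1))
  if (length(unique(scales)) != 1L)
    stop("cohorts mix log and linear scale; transform before merging")
  genes <- Reduce(intersect, lapply(cohorts, function(co) rownames(co$matrix)))
  if (!length(genes)) stop("no genes shared by all cohorts; cannot merge")
  mats <- lapply(cohorts, function(co) co$matrix[genes, , drop = FALSE])
  mat <- do.call(cbind, mats)
  if (anyDuplicated(colnames(mat)))
    colnames(mat) <- make.unique(colnames(mat), sep = "_")
  covs <- lapply(cohorts, function(co) {
    cv <- co$covariates
    if (is.null(cv)) cv <- data.frame(row.names = seq_len(ncol(co$matrix)))
    cv
  })
  all_cols <- unique(unlist(lapply(covs, names)))
  covariates <- NULL
  if (length(all_cols)) {
    covariates <- do.call(rbind, lapply(covs, function(cv) {
      for (cl in setdiff(all_cols, names(cv))) cv[[cl]] <- NA
      cv[, all_cols, drop = FALSE]
    }))
    rownames(covariates) <- colnames(mat)
  }
  expression_cohort(
    mat,
    group = unlist(lapply(cohorts, function(co) co$group), use.names = FALSE),
    cohort_id = merged_id %||% platforms[1],
    platform_id = platforms[1],
    covariates = covariates,
    is_log_scale = scales[1],
    batch = unlist(lapply(cohorts, function(co) rep(co$cohort_id, ncol(co$matrix))),
                   use.names = FALSE))
}

#' Center batches gene-wise
#'
#' For every gene, each batch's mean is shifted to the gene's grand mean
#' (location adjustment only; within-batch scale and group proportions are
#' untouched). Batches of size one cannot be centered and are left alone
#' with a warning. This is a deliberately simple location-only adjustment;
#' see the methods vignette for what it does and does not remove.
#'
#' @param cohort A merged [expression_cohort()].
#' @param batch Per-sample batch labels; defaults to the cohort's stored
#'   batch vector.
#' @return The centered cohort.
#' @export
batch_center <- function(cohort, batch = cohort$batch) {
  stopifnot(inherits(cohort, "expression_cohort"))
  batch <- as.character(batch)
  if (length(batch) != ncol(cohort$matrix))
    stop("`batch` must have one label per sample")
  tab <- table(batch)
  if (length(tab) < 2L) return(cohort)
  singletons <- names(tab)[tab == 1L]
  if (length(singletons))
    warning(sprintf("batch(es) of size 1 left uncentered: %s",
                    paste(singletons, collapse = ", ")))
  grand <- rowMeans(cohort$matrix)
  for (b in setdiff(names(tab), singletons)) {
    idx <- which(batch == b)
    bm <- rowMeans(cohort$matrix[, idx, drop = FALSE])
    cohort$matrix[, idx] <- cohort$matrix[, idx, drop = FALSE] - bm + grand
  }
  cohort
}

#' Summarize one gene's expression by group
#'
#' @param cohort An [expression_cohort()].
#' @param gene Gene symbol (uppercased for matching).
#' @return A [group_summary()]; its `usable` flag is `FALSE` when either
#'   group has fewer than two samples.
#' @export
summarize_group <- function(cohort, gene) {
  stopifnot(inherits(cohort, "expression_cohort"))
  gene <- toupper(gene)
  if (!gene %in% rownames(cohort$matrix))
    stop(sprintf("gene '%s' not present in cohort '%s'", gene, cohort$cohort_id))
  v <- cohort$matrix[gene, ]
  t1 <- v[cohort$group == "tumor"]
  t0 <- v[cohort$group == "control"]
  if (!length(t1) || !length(t0))
    stop(sprintf("cohort '%s' lacks a tumor or control group", cohort$cohort_id))
  sd_or_zero <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
  group_summary(length(t1), mean(t1), sd_or_zero(t1),
                length(t0), mean(t0), sd_or_zero(t0),
                label = cohort$cohort_id)
}
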