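#!/usr/bin/env Rscript
# Stage 3: diagnostic-accuracy meta-analysis of the target gene.
#
# Per-cohort ROC curves with Youden-optimal cutoffs, 2x2 classification
# tables, logit-pooled sensitivity and specificity, the Moses-Littenberg
# summary ROC, and Fagan post-test probabilities at a 20% pre-test
# probability.

suppressPackageStartupMessages(library(metamarker))

seed <- 20260920L
spec <- simulation_spec(seed = seed)
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_cohorts(spec)

per <- lapply(names(sim$cohorts), function(id) {
  co <- sim$cohorts[[id]]
  v <- co$matrix[spec$target, ]
  roc <- roc_curve(v, co$group)
  cut <- youden_cutoff(roc)
  tab <- to_two_by_two(v, co$group, cut$cutoff)
  data.frame(cohort = id, auc = roc$auc, cutoff = cut$cutoff,
             sens = cut$sens, spec = cut$spec,
             tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn)
})
per_df <- do.call(rbind, per)
write.table(per_df, file.path(out, "roc_per_cohort.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("per-cohort AUC: median %.3f (range %.3f-%.3f)\n",
            median(per_df$auc), min(per_df$auc), max(per_df$auc)))

studies <- lapply(seq_len(nrow(per_df)), function(i)
  structure(list(tp = per_df$tp[i], fp = per_df$fp[i],
                 fn = per_df$fn[i], tn = per_df$tn[i],
                 cutoff = per_df$cutoff[i]), class = "diagnostic_study"))
acc <- pool_accuracy(studies)
cat(sprintf("pooled sensitivity %.3f [%.3f, %.3f]; specificity %.3f [%.3f, %.3f]\n",
            acc$sens$pooled, acc$sens$ci_low, acc$sens$ci_high,
            acc$spec$pooled, acc$spec$ci_low, acc$spec$ci_high))
cat(sprintf("LR+ %.2f, LR- %.3f, DOR %.1f\n", acc$lr_pos, acc$lr_neg, acc$dor))

sr <- sroc(studies)
write.table(sr$curve, file.path(out, "sroc_curve.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("summary ROC AUC: %.3f\n", sr$auc))

fg <- fagan(0.20, acc$sens$pooled, acc$spec$pooled)
cat(sprintf("Fagan at 20%% pre-test: positive result -> %.1f%%, negative result -> %.1f%%\n",
            100 * fg$post_pos, 100 * fg$post_neg))
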