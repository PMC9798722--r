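#!/usr/bin/env Rscript
# Stage 4: DEG / co-expressed-gene screening and vote counting.
#
# Per-cohort screens (|log2FC| > 1 with BH-adjusted Welch p < 0.05;
# |r| >= 0.3 with p < 0.05 against the target across all samples), vote
# counting at >= 5 supporting cohorts per direction, pooled-SMD confirmation
# of the voted DEGs, and the intersections: set A = confirmed-up genes that
# are positive co-expression partners, set B = confirmed-down with negative
# partners.

suppressPackageStartupMessages(library(metamarker))

seed <- 20260920L
spec <- simulation_spec(seed = seed)
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_cohorts(spec)

de_lists <- lapply(sim$cohorts, function(co) {
  df <- de_screen(co)
  df[df$pass, c("gene", "direction")]
})
ceg_lists <- lapply(sim$cohorts, function(co) {
  df <- ceg_screen(co, spec$target)
  df[df$pass, c("gene", "direction")]
})
cat(sprintf("per-cohort passing genes: DE median %d, co-expression median %d\n",
            median(vapply(de_lists, nrow, integer(1))),
            median(vapply(ceg_lists, nrow, integer(1)))))

de_votes <- vote_count(de_lists, 5)
ceg_votes <- vote_count(ceg_lists, 5)
write.table(de_votes, file.path(out, "de_votes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ceg_votes, file.path(out, "ceg_votes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("vote counting (>=5 cohorts): %d DEGs (%d up / %d down), %d CEGs (%d +r / %d -r)\n",
            nrow(de_votes), sum(de_votes$direction == "up"),
            sum(de_votes$direction == "down"),
            nrow(ceg_votes), sum(ceg_votes$direction == "pos"),
            sum(ceg_votes$direction == "neg")))

confirmed <- smd_confirm(sim$cohorts, unique(de_votes$gene))
write.table(confirmed, file.path(out, "smd_confirmed.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("SMD confirmation: %d up, %d down (95%% CI excluding zero)\n",
            sum(confirmed$confirmed == "up"), sum(confirmed$confirmed == "down")))

sets <- intersect_sets(
  up = confirmed$gene[confirmed$confirmed == "up"],
  down = confirmed$gene[confirmed$confirmed == "down"],
  pos_r = ceg_votes$gene[ceg_votes$direction == "pos"],
  neg_r = ceg_votes$gene[ceg_votes$direction == "neg"],
  target = spec$target)
writeLines(sets$A, file.path(out, "gene_set_A.txt"))
writeLines(sets$B, file.path(out, "gene_set_B.txt"))

truth <- sim$truth$deg
recovered_A <- mean(sets$A %in% truth$gene[truth$direction == "up"])
cat(sprintf("gene set A: %d genes (%.0f%% planted up-regulated); gene set B: %d genes\n",
            length(sets$A), 100 * recovered_A, length(sets$B)))
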