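.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the whole multi-cohort biomarker evaluation on simulated data
#'
#' Executes, in order: synthetic-data generation, per-cohort target-gene
#' summaries, SMD meta-analysis (subgroups mRNA cohorts vs IHC,
#' leave-one-out, Begg's test), diagnostic meta-analysis (per-cohort ROC,
#' Youden cutoffs, pooled sensitivity/specificity, sROC, Fagan), DEG/CEG
#' screening with vote counting, SMD confirmation and gene-set
#' intersection, and the downstream IHC, clinical-subgroup, survival, hub
#' and over-representation analyses. Everything is deterministic given
#' `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param target Target gene symbol; defaults to the spec's target. A gene
#'   absent from the simulated cohorts aborts with a stage-named error.
#' @param pretest Pre-test probability for the Fagan step (default 0.2).
#' @param min_repetition Vote-count threshold (default 5).
#' @param lfc_threshold,alpha,r_threshold Screening thresholds (defaults
#'   1, 0.05, 0.3).
#' @param out_dir Optional directory; when given, result tables are written
#'   as TSV plus a JSON summary carrying the seed.
#' @return A named list with one element per stage plus `config`.
#' @export
run_pipeline <- function(spec = simulation_spec(),
                         target = spec$target,
                         pretest = 0.2,
                         min_repetition = 5L,
                         lfc_threshold = 1, alpha = 0.05, r_threshold = 0.3,
                         out_dir = NULL) {
  target <- toupper(target)

  sim <- .stage("simulate", simulate_cohorts(spec))
  cohorts <- sim$cohorts
  ihc_records <- .stage("simulate", simulate_ihc(spec))

  meta <- .stage("meta_effect", {
    summaries <- lapply(cohorts, summarize_group, gene = target)
    effects <- lapply(summaries, smd, correction = "cohen")
    ihc_by_group <- split(ihc_records$irs, ihc_records$group)
    ihc_summary <- group_summary(
      length(ihc_by_group$tumor), mean(ihc_by_group$tumor), stats::sd(ihc_by_group$tumor),
      length(ihc_by_group$control), mean(ihc_by_group$control), stats::sd(ihc_by_group$control),
      label = "in_house_ihc")
    all_effects <- c(unname(effects), list(smd(ihc_summary, "cohen")))
    list(summaries = summaries,
         ihc_summary = ihc_summary,
         effects = all_effects,
         subgroups = subgroup_pool(all_effects,
                                   c(rep("mRNA", length(effects)), "IHC")),
         pooled = pool(all_effects, "auto"),
         leave_one_out = leave_one_out(all_effects, "auto"),
         beggs = beggs_test(all_effects))
  })

  diagnostic <- .stage("meta_diagnostic", {
    per_cohort <- lapply(cohorts, function(co) {
      v <- co$matrix[target, ]
      roc <- roc_curve(v, co$group)
      cut <- youden_cutoff(roc)
      list(auc = roc$auc, cutoff = cut,
           table = to_two_by_two(v, co$group, cut$cutoff))
    })
    studies <- lapply(per_cohort, `[[`, "table")
    acc <- pool_accuracy(studies, "auto")
    list(per_cohort = per_cohort,
         accuracy = acc,
         sroc = sroc(studies),
         fagan = fagan(pretest, acc$sens$pooled, acc$spec$pooled))
  })

  screen <- .stage("screen", {
    de_lists <- lapply(cohorts, function(co) {
      df <- de_screen(co, lfc_threshold, alpha)
      df[df$pass, c("gene", "direction"), drop = FALSE]
    })
    ceg_lists <- lapply(cohorts, function(co) {
      df <- ceg_screen(co, target, r_threshold, alpha)
      df[df$pass, c("gene", "direction"), drop = FALSE]
    })
    de_votes <- vote_count(de_lists, min_repetition)
    ceg_votes <- vote_count(ceg_lists, min_repetition)
    confirmed <- smd_confirm(cohorts, unique(de_votes$gene))
    sets <- intersect_sets(
      up = confirmed$gene[confirmed$confirmed == "up"],
      down = confirmed$gene[confirmed$confirmed == "down"],
      pos_r = ceg_votes$gene[ceg_votes$direction == "pos"],
      neg_r = ceg_votes$gene[ceg_votes$direction == "neg"],
      target = target)
    list(de_votes = de_votes, ceg_votes = ceg_votes,
         confirmed = confirmed, sets = sets)
  })

  downstream <- .stage("downstream", {
    ihc_t <- two_sample_t(meta$ihc_summary, "welch")
    big <- cohorts[[which.max(vapply(cohorts, function(co) ncol(co$matrix), numeric(1)))]]
    tumor_idx <- which(big$group == "tumor")
    expr <- big$matrix[target, tumor_idx]
    age_grp <- ifelse(big$covariates$age[tumor_idx] < 60, "age<60", "age>=60")
    age_effect <- clinical_subgroup_effect(expr, age_grp, variant = "welch")
    stage_grp <- ifelse(big$covariates$stage[tumor_idx] %in% c("I", "II"),
                        "stage I/II", "stage III/IV")
    stage_effect <- clinical_subgroup_effect(expr, stage_grp, variant = "welch")
    surv_tab <- simulate_survival(spec, expr)
    surv <- survival_median_split(expr, surv_tab$time, surv_tab$event)
    universe <- rownames(big$matrix)
    gene_sets <- list(planted_up = sim$truth$deg$gene[sim$truth$deg$direction == "up"],
                      planted_down = sim$truth$deg$gene[sim$truth$deg$direction == "down"],
                      planted_coexpr = sim$truth$ceg$gene)
    query <- if (length(screen$sets$A)) screen$sets$A else screen$de_votes$gene
    enrichment <- if (length(query)) ora(query, universe, gene_sets) else NULL
    hub_edges <- .truth_edge_list(sim$truth, target)
    list(ihc_t = ihc_t, age_effect = age_effect, stage_effect = stage_effect,
         survival = surv,
         enrichment = enrichment,
         hubs = hub_rank(hub_edges, 10L))
  })

  result <- list(
    config = list(seed = spec$seed, target = target, pretest = pretest,
                  min_repetition = min_repetition,
                  lfc_threshold = lfc_threshold, alpha = alpha,
                  r_threshold = r_threshold,
                  n_genes = spec$n_genes, n_cohorts = nrow(spec$cohorts)),
    truth = sim$truth,
    meta_effect = meta,
    meta_diagnostic = diagnostic,
    screen = screen,
    downstream = downstream)

  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

# deterministic interactome built from the planted truth: the target is wired
# to every co-expression-block gene, and consecutive planted DEGs are chained,
# giving known degrees for the hub step without random edges
.truth_edge_list <- function(truth, target) {
  co <- truth$ceg$gene
  deg <- truth$deg$gene
  edges <- rbind(
    data.frame(node_a = target, node_b = co, stringsAsFactors = FALSE),
    if (length(deg) > 1L)
      data.frame(node_a = deg[-length(deg)], node_b = deg[-1L],
                 stringsAsFactors = FALSE))
  edges$score <- 0.9
  edges
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  eff <- result$meta_effect$effects
  wt(data.frame(label = vapply(eff, `[[`, character(1), "label"),
                smd = vapply(eff, `[[`, numeric(1), "estimate"),
                ci_low = vapply(eff, `[[`, numeric(1), "ci_low"),
                ci_high = vapply(eff, `[[`, numeric(1), "ci_high")),
     "forest.tsv")
  wt(result$screen$de_votes, "de_votes.tsv")
  wt(result$screen$ceg_votes, "ceg_votes.tsv")
  wt(result$screen$confirmed, "smd_confirmed.tsv")
  wt(data.frame(gene = result$screen$sets$A), "gene_set_A.tsv")
  wt(data.frame(gene = result$screen$sets$B), "gene_set_B.tsv")
  wt(result$meta_diagnostic$sroc$curve, "sroc_curve.tsv")
  wt(result$downstream$hubs, "hubs.tsv")
  if (!is.null(result$downstream$enrichment))
    wt(result$downstream$enrichment, "enrichment.tsv")
  pooled <- result$meta_effect$pooled
  acc <- result$meta_diagnostic$accuracy
  summary <- list(
    config = result$config,
    pooled_smd = list(estimate = pooled$pooled, ci_low = pooled$ci_low,
                      ci_high = pooled$ci_high, model = pooled$model,
                      I2 = pooled$I2, tau2 = pooled$tau2),
    beggs_p = result$meta_effect$beggs$p,
    pooled_sens = acc$sens$pooled, pooled_spec = acc$spec$pooled,
    sroc_auc = result$meta_diagnostic$sroc$auc,
    fagan = result$meta_diagnostic$fagan,
    n_set_A = length(result$screen$sets$A),
    n_set_B = length(result$screen$sets$B),
    survival = list(hr = result$downstream$survival$hr,
                    p = result$downstream$survival$p))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
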