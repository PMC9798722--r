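#' Immunoreactivity score for one field
#'
#' The IRS of a stained field is the product of the staining-intensity
#' score (0 none, 1 weak, 2 moderate, 3 strong) and the stained-cell
#' proportion category (0-4), giving a score from 0 to 12.
#'
#' @param intensity Integer(ish) vector in {0,1,2,3}.
#' @param proportion_category Integer(ish) vector in {0,1,2,3,4}.
#' @return Integer vector of products in 0..12.
#' @export
irs <- function(intensity, proportion_category) {
  if (!all(intensity %in% 0:3))
    stop("intensity scores must be in {0, 1, 2, 3}")
  if (!all(proportion_category %in% 0:4))
    stop("proportion categories must be in {0, 1, 2, 3, 4}")
  as.integer(intensity) * as.integer(proportion_category)
}

#' Proportion category from the fraction of stained cells
#'
#' 0 when no cells stain; 1 for fractions up to 10%; 2 up to 50%; 3 up to
#' 80%; 4 above 80%. (The conventional printed bins "<10%" and "11-50%"
#' leave 10-11% unassigned; this implementation uses half-open bins
#' (0, 0.10], (0.10, 0.50], (0.50, 0.80], (0.80, 1].)
#'
#' @param fraction_stained Numeric vector in `[0, 1]`.
#' @return Integer vector in 0..4.
#' @export
proportion_category <- function(fraction_stained) {
  if (any(fraction_stained < 0 | fraction_stained > 1))
    stop("stained fraction must lie in [0, 1]")
  as.integer(cut(fraction_stained, c(-Inf, 0, 0.10, 0.50, 0.80, 1),
                 labels = FALSE)) - 1L
}

#' Aggregate per-field scores into a specimen-level IRS
#'
#' Specimens are scored on several (nominally ten) high-power fields; the
#' specimen IRS is the mean (default) or median of the per-field products.
#'
#' @param intensity,proportion_category Per-field scores (equal length,
#'   >= 1 field).
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return Specimen IRS in `[0, 12]`.
#' @export
specimen_irs <- function(intensity, proportion_category,
                         aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!length(intensity)) stop("at least one field is required")
  if (length(intensity) != length(proportion_category))
    stop("intensity and proportion vectors must have equal length")
  scores <- irs(intensity, proportion_category)
  if (aggregate == "mean") mean(scores) else stats::median(scores)
}

#' Effect size of a biomarker across a binary clinical stratum
#'
#' Splits values (expression or IRS) by a binary covariate (e.g. age < 60
#' vs >= 60, male vs female, stage I/II vs III/IV), then reuses
#' [two_sample_t()] and [smd()] on the stratified summary. The first
#' stratum level plays the "tumor"/case role, so signs read
#' first minus second.
#'
#' @param values Numeric vector.
#' @param stratum Two-level factor/character/logical, one entry per value.
#' @param variant t variant (see [two_sample_t()]).
#' @param correction SMD flavor (see [smd()]).
#' @return List `summary` ([group_summary()]), `t_test`, `smd`.
#' @export
clinical_subgroup_effect <- function(values, stratum, variant = "welch",
                                     correction = "cohen") {
  keep <- !is.na(stratum) & !is.na(values)
  values <- values[keep]
  stratum <- as.factor(as.character(stratum[keep]))
  if (nlevels(stratum) != 2L)
    stop("the stratifying covariate must have exactly two non-missing levels")
  a <- values[stratum == levels(stratum)[1]]
  b <- values[stratum == levels(stratum)[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop("both strata need at least two observations")
  gs <- group_summary(length(a), mean(a), stats::sd(a),
                      length(b), mean(b), stats::sd(b),
                      label = paste(levels(stratum), collapse = " vs "))
  list(summary = gs,
       t_test = two_sample_t(gs, variant),
       smd = smd(gs, correction))
}

#' Median-split survival analysis
#'
#' Samples at or above the median marker value form the high group. Returns
#' Kaplan-Meier curves per group, the log-rank statistic, and the hazard
#' ratio of high vs low from a single-covariate Cox partial likelihood,
#' all computed with the survival package. The simple log-rank O/E ratio
#' `(O_high/E_high) / (O_low/E_low)` is also reported as `hr_oe`; it is
#' attenuated toward 1 for large effects (see the methods vignette), which
#' is why the Cox estimate is the primary `hr`.
#'
#' @param expression Marker values.
#' @param time Follow-up times (months).
#' @param event Status, 1 = event observed, 0 = censored.
#' @return List `km` (a `survfit` object over groups), `logrank_chi2`, `p`,
#'   `hr` (Cox, high vs low), `hr_oe` (log-rank O/E ratio), `group` (the
#'   high/low assignment used).
#' @export
survival_median_split <- function(expression, time, event) {
  stopifnot(length(expression) == length(time), length(time) == length(event))
  if (sum(event) < 2L) stop("need at least two observed events")
  grp <- factor(ifelse(expression >= stats::median(expression), "high", "low"),
                levels = c("low", "high"))
  if (nlevels(droplevels(grp)) < 2L)
    stop("median split produced a single group (constant marker?)")
  surv <- survival::Surv(time, event)
  sd_ <- survival::survdiff(surv ~ grp)
  # observed/expected order follows the factor levels: low then high
  hr_oe <- (sd_$obs[2] / sd_$exp[2]) / (sd_$obs[1] / sd_$exp[1])
  fit <- survival::coxph(surv ~ grp)
  list(km = survival::survfit(surv ~ grp),
       logrank_chi2 = sd_$chisq,
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       hr = unname(exp(stats::coef(fit)[["grphigh"]])),
       hr_oe = unname(hr_oe),
       group = grp)
}

#' Degree-based hub ranking of an interaction network
#'
#' Nodes are ranked by degree (descending, ties broken alphabetically) and
#' the top `k` returned; every node tied with the k-th degree is included.
#'
#' @param edges An `edge_list` (see [read_edge_list()]) or any data.frame
#'   whose first two columns are node symbols.
#' @param k Number of hubs requested (> 0).
#' @return data.frame `gene`, `degree`, sorted.
#' @export
hub_rank <- function(edges, k) {
  if (!is.numeric(k) || k <= 0) stop("`k` must be a positive integer")
  if (!nrow(edges)) stop("empty edge list: no nodes to rank")
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  deg <- igraph::degree(g)
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  k <- min(as.integer(k), nrow(out))
  thresh <- out$degree[k]
  out <- out[out$degree >= thresh, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of seeing
#' at least the observed overlap between the query and the set, given the
#' universe; BH adjustment across sets. Sets are intersected with the
#' universe first; query genes outside the universe are dropped with a
#' warning.
#'
#' @param query Character vector of genes of interest.
#' @param universe Character vector of all assayed genes.
#' @param sets A `gene_set_collection` (see [read_gmt()]) or named list of
#'   character vectors.
#' @return data.frame `term`, `set_size`, `overlap`, `p`, `padj`, sorted by
#'   ascending p.
#' @export
ora <- function(query, universe, sets) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after intersecting with the universe")
  N <- length(universe); q <- length(query)
  rows <- lapply(names(sets), function(tm) {
    members <- intersect(toupper(sets[[tm]]), universe)
    K <- length(members)
    if (!K) return(NULL)
    ov <- length(intersect(query, members))
    p <- stats::phyper(ov - 1, K, N - K, q, lower.tail = FALSE)
    data.frame(term = tm, set_size = K, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$padj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
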