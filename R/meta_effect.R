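#' Standardized mean difference for one cohort
#'
#' Computes the tumor-minus-control standardized mean difference from a
#' [group_summary()]. With `correction = "cohen"` the estimate is Cohen's d
#' on the pooled SD
#' `s_p = sqrt(((n1-1) sd1^2 + (n0-1) sd0^2) / (n1+n0-2))`;
#' `"hedges"` multiplies by the small-sample factor
#' `J = 1 - 3 / (4(n1+n0-2) - 1)`. The large-sample variance is
#' `(n1+n0)/(n1 n0) + d^2 / (2(n1+n0))` and the 95% CI uses normal
#' quantiles.
#'
#' @param summary A [group_summary()].
#' @param correction `"cohen"` (default) or `"hedges"`.
#' @return A `study_effect` list: `estimate`, `variance`, `ci_low`,
#'   `ci_high`, `label`.
#' @export
smd <- function(summary, correction = c("cohen", "hedges")) {
  correction <- match.arg(correction)
  stopifnot(inherits(summary, "group_summary"))
  if (!summary$usable)
    stop("SMD needs at least two samples per group")
  n1 <- summary$n1; n0 <- summary$n0
  if (summary$sd1 == 0 && summary$sd0 == 0)
    stop("both group SDs are zero: SMD undefined")
  sp <- sqrt(((n1 - 1) * summary$sd1^2 + (n0 - 1) * summary$sd0^2) / (n1 + n0 - 2))
  d <- (summary$mean1 - summary$mean0) / sp
  if (correction == "hedges") d <- d * (1 - 3 / (4 * (n1 + n0 - 2) - 1))
  v <- (n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0))
  study_effect(d, v, label = summary$label)
}

#' Construct a study effect (estimate + sampling variance)
#'
#' @param estimate Effect estimate (e.g. an SMD).
#' @param variance Sampling variance, strictly positive.
#' @param label Study label.
#' @param conf_level Confidence level for the normal-quantile CI.
#' @return A `study_effect` list.
#' @export
study_effect <- function(estimate, variance, label = NA_character_,
                         conf_level = 0.95) {
  if (!is.finite(variance) || variance <= 0)
    stop("`variance` must be a positive number")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(estimate = estimate, variance = variance,
                 ci_low = estimate - z * sqrt(variance),
                 ci_high = estimate + z * sqrt(variance),
                 label = as.character(label)),
            class = "study_effect")
}

#' @export
print.study_effect <- function(x, ...) {
  cat(sprintf("study_effect%s: %.4f [%.4f, %.4f] (var %.4g)\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$estimate, x$ci_low, x$ci_high, x$variance))
  invisible(x)
}

.effects_to_df <- function(effects) {
  if (inherits(effects, "study_effect")) effects <- list(effects)
  data.frame(
    estimate = vapply(effects, function(e) e$estimate, numeric(1)),
    variance = vapply(effects, function(e) e$variance, numeric(1)),
    label = vapply(effects, function(e) e$label %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity test and I-squared
#'
#' Fixed-effect weights `w_i = 1/v_i`; `Q = sum w_i (e_i - e_bar)^2` with
#' `e_bar` the fixed-effect mean; `I2 = max(0, (Q - df)/Q)`.
#'
#' @param effects List of [study_effect()]s (k >= 2).
#' @return List `Q`, `df`, `p`, `I2`.
#' @export
heterogeneity <- function(effects) {
  df_ <- .effects_to_df(effects)
  k <- nrow(df_)
  if (k < 2L) stop("heterogeneity needs at least two studies")
  w <- 1 / df_$variance
  mu <- sum(w * df_$estimate) / sum(w)
  Q <- sum(w * (df_$estimate - mu)^2)
  df <- k - 1L
  list(Q = Q, df = df,
       p = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - df) / Q) else 0)
}

#' Pool study effects (fixed / DerSimonian-Laird random effects)
#'
#' `model = "fixed"` uses inverse-variance weights. `"random"` uses the
#' DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - df) / C)`, `C = sum(w) - sum(w^2)/sum(w)`, and
#' weights `1/(v_i + tau2)`. `"auto"` follows the conventional rule of
#' selecting the random-effects model when I2 > 50% or the heterogeneity
#' p-value < 0.05, and the fixed (common) effect model otherwise. CIs use
#' normal quantiles.
#'
#' @param effects List of [study_effect()]s (k >= 2).
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return A `meta_result` list: `pooled`, `se`, `ci_low`, `ci_high`, `Q`,
#'   `df`, `p_het`, `I2`, `tau2`, `model`, `k`.
#' @export
pool <- function(effects, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  df_ <- .effects_to_df(effects)
  k <- nrow(df_)
  if (k < 2L) stop("pooling needs at least two studies")
  het <- heterogeneity(effects)
  if (model == "auto")
    model <- if (het$I2 > 0.5 || het$p < 0.05) "random" else "fixed"
  w <- 1 / df_$variance
  tau2 <- 0
  if (model == "random") {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (het$Q - het$df) / C)
    w <- 1 / (df_$variance + tau2)
  }
  pooled <- sum(w * df_$estimate) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(0.975)
  structure(list(pooled = pooled, se = se,
                 ci_low = pooled - z * se, ci_high = pooled + z * se,
                 Q = het$Q, df = het$df, p_het = het$p, I2 = het$I2,
                 tau2 = tau2, model = model, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result (%s, k=%d): %.4f [%.4f, %.4f]; Q=%.3f (df %d, p=%.3g), I2=%.1f%%, tau2=%.4g\n",
              x$model, x$k, x$pooled, x$ci_low, x$ci_high,
              x$Q, x$df, x$p_het, 100 * x$I2, x$tau2))
  invisible(x)
}

.single_study_result <- function(effect) {
  structure(list(pooled = effect$estimate, se = sqrt(effect$variance),
                 ci_low = effect$ci_low, ci_high = effect$ci_high,
                 Q = 0, df = 0L, p_het = NA_real_, I2 = 0, tau2 = 0,
                 model = "single", k = 1L),
            class = "meta_result")
}

#' Subgroup meta-analysis
#'
#' Pools within each subgroup (model auto) and overall. A singleton
#' subgroup is reported as the study's own effect and CI, unpooled.
#'
#' @param effects List of [study_effect()]s.
#' @param subgroup Character vector of subgroup labels, one per effect.
#' @param model Model passed to [pool()] (subgroups and overall alike).
#' @return List with `subgroups` (named list of `meta_result`) and
#'   `overall`.
#' @export
subgroup_pool <- function(effects, subgroup, model = "auto") {
  if (inherits(effects, "study_effect")) effects <- list(effects)
  if (length(subgroup) != length(effects))
    stop("one subgroup label per effect is required")
  subgroup <- as.character(subgroup)
  out <- list()
  for (g in unique(subgroup)) {
    idx <- which(subgroup == g)
    out[[g]] <- if (length(idx) == 1L) .single_study_result(effects[[idx]])
                else pool(effects[idx], model)
  }
  list(subgroups = out, overall = pool(effects, model))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the remaining k-1 studies with each study omitted in turn.
#'
#' @param effects List of [study_effect()]s (k >= 3).
#' @param model Model passed to [pool()].
#' @return Named list of `meta_result`s, one per omitted study.
#' @export
leave_one_out <- function(effects, model = "auto") {
  if (inherits(effects, "study_effect")) effects <- list(effects)
  k <- length(effects)
  if (k < 3L) stop("leave-one-out needs at least three studies")
  labels <- vapply(effects, function(e) e$label %||% NA_character_, character(1))
  if (anyNA(labels) || anyDuplicated(labels)) labels <- paste0("study", seq_len(k))
  out <- lapply(seq_len(k), function(i) pool(effects[-i], model))
  names(out) <- labels
  out
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Standardizes each effect against the fixed-effect mean,
#' `t_i = (e_i - e_bar) / sqrt(v_i - 1/sum(w))`, then tests Kendall
#' concordance between the deviates and the sampling variances. Ties
#' contribute to neither the concordant (P) nor discordant (Q) count. The
#' normal deviate uses the continuity correction
#' `z = (|P - Q| - 1) / sqrt(k(k-1)(2k+5)/18)` (no correction when
#' P = Q), with a two-sided p-value.
#'
#' @param effects List of [study_effect()]s (k >= 3).
#' @return List `tau`, `P`, `Q`, `z`, `p`.
#' @export
beggs_test <- function(effects) {
  df_ <- .effects_to_df(effects)
  k <- nrow(df_)
  if (k < 3L) stop("Begg's test needs at least three studies")
  w <- 1 / df_$variance
  mu <- sum(w * df_$estimate) / sum(w)
  dev <- (df_$estimate - mu) / sqrt(df_$variance - 1 / sum(w))
  P <- 0L; Qd <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- (dev[i] - dev[j]) * (df_$variance[i] - df_$variance[j])
      if (s > 0) P <- P + 1L else if (s < 0) Qd <- Qd + 1L
    }
  }
  denom <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  diff <- P - Qd
  z <- if (diff == 0) 0 else sign(diff) * (abs(diff) - 1) / denom
  list(tau = diff / (k * (k - 1) / 2), P = P, Q = Qd, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Pool Pearson correlations via Fisher's z
#'
#' Each study's coefficient is transformed to `z_i = atanh(r_i)` with
#' standard error `1/sqrt(n_i - 3)`, pooled on the z scale with [pool()],
#' and the pooled value and CI back-transformed with `tanh`.
#'
#' @param r Numeric vector of Pearson coefficients, all strictly inside
#'   (-1, 1).
#' @param n Integer vector of per-study sample sizes (all >= 4).
#' @param labels Optional study labels.
#' @param model Model passed to [pool()] when k >= 2.
#' @return A `meta_result` on the correlation scale (elements `Q`, `I2`,
#'   `tau2` remain on the z scale; `se` is the pooled z-scale SE).
#' @export
pool_correlations <- function(r, n, labels = NULL, model = "auto") {
  if (length(r) != length(n)) stop("`r` and `n` must have equal length")
  if (any(abs(r) >= 1)) stop("correlations must satisfy |r| < 1")
  if (any(n < 4L)) stop("each study needs n >= 4 (se of z requires n - 3 > 0)")
  if (is.null(labels)) labels <- paste0("study", seq_along(r))
  z <- atanh(r)
  v <- 1 / (n - 3)
  effects <- Map(function(zi, vi, li) study_effect(zi, vi, label = li), z, v, labels)
  res <- if (length(r) == 1L) .single_study_result(effects[[1]]) else pool(effects, model)
  res$pooled <- tanh(res$pooled)
  res$ci_low <- tanh(res$ci_low)
  res$ci_high <- tanh(res$ci_high)
  res$scale <- "r (pooled on Fisher z)"
  res
}
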