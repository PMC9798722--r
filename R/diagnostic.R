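#' Two-sample t statistic from group summaries
#'
#' `"student"` is the pooled-variance t with `df = n1 + n0 - 2`; `"welch"`
#' uses `t = (mean1 - mean0) / sqrt(sd1^2/n1 + sd0^2/n0)` with the
#' Welch-Satterthwaite df. `"auto"` runs an F test of variance equality at
#' alpha = 0.05 and picks Welch when it rejects. The sign follows
#' tumor minus control.
#'
#' @param summary A [group_summary()].
#' @param variant `"auto"`, `"student"` or `"welch"`.
#' @return List `t`, `df`, `p` (two-sided), `variant`.
#' @export
two_sample_t <- function(summary, variant = c("auto", "student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(summary, "group_summary"))
  if (!summary$usable) stop("t test needs at least two samples per group")
  n1 <- summary$n1; n0 <- summary$n0
  s1 <- summary$sd1; s0 <- summary$sd0
  if (s1 == 0 && s0 == 0) stop("both group variances are zero: t undefined")
  if (variant == "auto") {
    f <- (max(s1, s0) / min(s1, s0))^2
    dfn <- if (s1 >= s0) n1 - 1 else n0 - 1
    dfd <- if (s1 >= s0) n0 - 1 else n1 - 1
    p_f <- 2 * stats::pf(f, dfn, dfd, lower.tail = FALSE)
    variant <- if (min(p_f, 1) < 0.05) "welch" else "student"
  }
  delta <- summary$mean1 - summary$mean0
  if (variant == "student") {
    sp2 <- ((n1 - 1) * s1^2 + (n0 - 1) * s0^2) / (n1 + n0 - 2)
    if (sp2 <= 0) stop("zero pooled variance: t undefined")
    t <- delta / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  } else {
    a <- s1^2 / n1; b <- s0^2 / n0
    t <- delta / sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n0 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), variant = variant)
}

#' Empirical ROC curve and AUC
#'
#' Tumor is the positive class and higher expression is more positive.
#' Curve points are generated at every distinct threshold (rule: positive
#' iff value >= cutoff), bracketed by the (0,0) and (1,1) endpoints. The
#' AUC is the trapezoidal area under the curve, which equals the
#' Mann-Whitney statistic `U / (n1 n0)` with ties counted one half.
#'
#' @param values Per-sample expression values.
#' @param labels Per-sample `"tumor"`/`"control"` labels.
#' @return List `points` (data.frame `cutoff`, `sens`, `spec`, `fpr`) and
#'   `auc`.
#' @export
roc_curve <- function(values, labels) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  pos <- values[labels == "tumor"]
  neg <- values[labels == "control"]
  if (!length(pos) || !length(neg))
    stop("both tumor and control samples are required for a ROC curve")
  cuts <- sort(unique(values), decreasing = TRUE)
  sens <- vapply(cuts, function(ct) mean(pos >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(neg < ct), numeric(1))
  points <- data.frame(cutoff = c(Inf, cuts), sens = c(0, sens),
                       spec = c(1, spec), fpr = c(0, 1 - spec))
  # last point (cutoff = min value) already has sens = 1, fpr = 1
  auc <- sum(diff(points$fpr) * (utils::head(points$sens, -1) + utils::tail(points$sens, -1)) / 2)
  list(points = points, auc = auc)
}

#' Youden-optimal cutoff from a ROC curve
#'
#' Maximizes J = sens + spec - 1; ties are broken toward the lower cutoff
#' (the more sensitive operating point). The degenerate endpoint at
#' `cutoff = Inf` is never returned.
#'
#' @param roc The result of [roc_curve()].
#' @return List `cutoff`, `sens`, `spec`, `j`.
#' @export
youden_cutoff <- function(roc) {
  pts <- roc$points[is.finite(roc$points$cutoff), , drop = FALSE]
  if (!nrow(pts)) stop("degenerate ROC: no finite thresholds")
  j <- pts$sens + pts$spec - 1
  best <- which(j == max(j))
  pick <- best[which.min(pts$cutoff[best])]
  list(cutoff = pts$cutoff[pick], sens = pts$sens[pick],
       spec = pts$spec[pick], j = j[pick])
}

#' Dichotomize a cohort at a cutoff into a 2x2 diagnostic table
#'
#' @param values,labels As in [roc_curve()].
#' @param cutoff Finite threshold; value >= cutoff is called positive.
#' @return A `diagnostic_study` list: `tp`, `fp`, `fn`, `tn`, `cutoff`.
#' @export
to_two_by_two <- function(values, labels, cutoff) {
  stopifnot(is.finite(cutoff))
  labels <- as.character(labels)
  pos <- labels == "tumor"
  called <- values >= cutoff
  structure(list(tp = sum(called & pos), fp = sum(called & !pos),
                 fn = sum(!called & pos), tn = sum(!called & !pos),
                 cutoff = cutoff),
            class = "diagnostic_study")
}

.cells <- function(study, correct = FALSE) {
  x <- c(tp = study$tp, fp = study$fp, fn = study$fn, tn = study$tn)
  if (correct && any(x == 0)) x <- x + 0.5
  x
}

#' Pool diagnostic accuracy across studies
#'
#' Sensitivity and specificity are pooled on the logit scale (per-study
#' variance `1/tp + 1/fn`, resp. `1/tn + 1/fp`) with [pool()] under the
#' given model, then back-transformed. Any study with a zero cell gets a
#' 0.5 continuity correction added to all four of its cells. Positive and
#' negative likelihood ratios and the diagnostic odds ratio are derived
#' from the pooled values.
#'
#' @param studies List of `diagnostic_study` objects (k >= 2).
#' @param model Model passed to [pool()].
#' @return List with `sens`, `spec` (each a `meta_result` back-transformed
#'   to the probability scale), `lr_pos`, `lr_neg`, `dor`.
#' @export
pool_accuracy <- function(studies, model = "auto") {
  if (length(studies) < 2L) stop("pooling accuracy needs at least two studies")
  mk <- function(num, den_other) {
    effects <- lapply(studies, function(st) {
      x <- .cells(st, correct = TRUE)
      p_logit <- log(x[[num]] / x[[den_other]])
      study_effect(p_logit, 1 / x[[num]] + 1 / x[[den_other]])
    })
    res <- pool(effects, model)
    res$pooled <- stats::plogis(res$pooled)
    res$ci_low <- stats::plogis(res$ci_low)
    res$ci_high <- stats::plogis(res$ci_high)
    res
  }
  sens <- mk("tp", "fn")
  spec <- mk("tn", "fp")
  lr_pos <- sens$pooled / (1 - spec$pooled)
  lr_neg <- (1 - sens$pooled) / spec$pooled
  list(sens = sens, spec = spec,
       lr_pos = lr_pos, lr_neg = lr_neg, dor = lr_pos / lr_neg)
}

#' Moses-Littenberg summary ROC curve
#'
#' For each study, `D = ln DOR` and `S = logit(sens) + logit(FPR)` (zero
#' cells receive the 0.5 correction). A least-squares line `D = a + bS`
#' defines the summary curve; for a false-positive rate x with
#' `logit(sens) = (a + (1+b) logit(x)) / (1 - b)`. The AUC is the
#' trapezoidal area over an equally spaced FPR grid. When the studies give
#' S no spread (all at one operating point) the slope is fixed at 0 and
#' the curve is the symmetric one through that point.
#'
#' @param studies List of `diagnostic_study` objects (k >= 3 recommended).
#' @param n_grid Number of FPR grid points (default 1001).
#' @return List `curve` (data.frame `fpr`, `sens`), `auc`, `a`, `b`.
#' @export
sroc <- function(studies, n_grid = 1001L) {
  if (length(studies) < 1L) stop("sROC needs at least one study")
  DS <- vapply(studies, function(st) {
    x <- .cells(st, correct = TRUE)
    ls <- log(x[["tp"]] / x[["fn"]])
    lf <- log(x[["fp"]] / x[["tn"]])
    c(D = ls - lf, S = ls + lf)
  }, numeric(2))
  D <- DS["D", ]; S <- DS["S", ]
  if (length(unique(signif(S, 10))) < 2L || stats::var(S) < 1e-12) {
    b <- 0; a <- mean(D)
  } else {
    fit <- stats::lm.fit(cbind(1, S), D)
    a <- fit$coefficients[[1]]; b <- fit$coefficients[[2]]
  }
  fpr <- seq(0, 1, length.out = n_grid)
  inner <- fpr[-c(1, n_grid)]
  lsens <- (a + (1 + b) * stats::qlogis(inner)) / (1 - b)
  sens <- c(0, stats::plogis(lsens), 1)
  curve <- data.frame(fpr = fpr, sens = sens)
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  list(curve = curve, auc = auc, a = a, b = b)
}

#' Fagan post-test probabilities
#'
#' Bayes' theorem on the odds scale: with pre-test odds `o = p/(1-p)`,
#' `post_pos = o LR+ / (1 + o LR+)` and `post_neg = o LR- / (1 + o LR-)`,
#' where `LR+ = sens/(1-spec)` and `LR- = (1-sens)/spec`.
#'
#' @param pretest Pre-test probability in (0, 1).
#' @param sens,spec Sensitivity and specificity in (0, 1).
#' @return List `post_pos`, `post_neg`, `lr_pos`, `lr_neg`.
#' @export
fagan <- function(pretest, sens, spec) {
  vals <- c(pretest = pretest, sens = sens, spec = spec)
  if (any(vals <= 0 | vals >= 1))
    stop("pretest, sens and spec must all lie strictly inside (0, 1)")
  lr_pos <- sens / (1 - spec)
  lr_neg <- (1 - sens) / spec
  odds <- pretest / (1 - pretest)
  list(post_pos = odds * lr_pos / (1 + odds * lr_pos),
       post_neg = odds * lr_neg / (1 + odds * lr_neg),
       lr_pos = lr_pos, lr_neg = lr_neg)
}
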