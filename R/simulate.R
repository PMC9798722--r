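#' Default multi-cohort design
#'
#' Nine cohorts with the tumor/control group sizes of a typical published
#' multi-platform compendium (including two merged-platform cohorts, very
#' small cohorts of 3 vs 3, and a heavily unbalanced 159 vs 4 cohort).
#'
#' @return data.frame `cohort_id`, `platform_id`, `n_tumor`, `n_control`.
#' @export
default_cohort_design <- function() {
  data.frame(
    cohort_id = sprintf("cohort%02d", 1:9),
    platform_id = sprintf("platform%02d", 1:9),
    n_tumor = c(159L, 58L, 7L, 3L, 25L, 3L, 25L, 18L, 10L),
    n_control = c(4L, 17L, 4L, 3L, 3L, 3L, 8L, 18L, 6L),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic multi-cohort study
#'
#' Bundles every knob of the generator: cohort design, planted target-gene
#' effect, planted up/down DEG blocks, a latent factor inducing
#' co-expression with the target, per-cohort batch shifts, and the survival
#' and IHC generating processes. All randomness derives from `seed`
#' ([simulate_ihc()] uses `seed + 1`, [simulate_survival()] `seed + 2`, so
#' each data type is independently reproducible).
#'
#' @param seed Integer root seed.
#' @param cohorts Cohort design data.frame (see [default_cohort_design()]).
#' @param n_genes Total genes per cohort (default 1000).
#' @param target Target gene symbol (default `"BUB1B"`).
#' @param target_smd Planted per-cohort SMD of the target gene (default 3).
#' @param n_up,n_down Numbers of planted up/down regulated genes
#'   (default 50 each).
#' @param de_delta Absolute tumor-control shift of planted DEGs, log2 units
#'   (default 2).
#' @param coexpr_size,coexpr_loading Size of the latent-factor block
#'   co-expressed with the target and its loading in (-1, 1)
#'   (defaults 50 and 0.7).
#' @param batch_shift_sd SD of gene-wise per-cohort baseline shifts
#'   (default 0.5).
#' @param noise_sd Residual SD on the log2 scale (default 1).
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#' @param stage_delta Extra target-gene shift in stage III/IV tumors
#'   (default 0: homogeneous planted effect).
#' @param survival List `baseline_hazard` (events/month for the low group),
#'   `hr` (hazard multiplier above the target median), `censor_rate`
#'   (independent exponential censoring rate).
#' @param ihc List `n_tumor`, `n_control`, `n_fields`, and the group-wise
#'   multinomial probabilities `tumor_intensity` (length 4, scores 0-3),
#'   `tumor_proportion` (length 5, categories 0-4), `control_intensity`,
#'   `control_proportion`. The defaults are calibrated so the expected
#'   specimen IRS is ~6.8 in tumors and ~2.2 in controls.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1L,
                            cohorts = default_cohort_design(),
                            n_genes = 1000L,
                            target = "BUB1B",
                            target_smd = 3,
                            n_up = 50L, n_down = 50L, de_delta = 2,
                            coexpr_size = 50L, coexpr_loading = 0.7,
                            batch_shift_sd = 0.5,
                            noise_sd = 1,
                            baseline_mean = 6, baseline_sd = 1,
                            stage_delta = 0,
                            survival = list(baseline_hazard = 0.02, hr = 4,
                                            censor_rate = 0.002),
                            ihc = list(
                              n_tumor = 110L, n_control = 47L, n_fields = 10L,
                              tumor_intensity = c(0.05, 0.10, 0.35, 0.50),
                              tumor_proportion = c(0.04, 0.08, 0.18, 0.28, 0.42),
                              control_intensity = c(0.25, 0.40, 0.25, 0.10),
                              control_proportion = c(0.15, 0.25, 0.30, 0.22, 0.08))) {
  stopifnot(is.data.frame(cohorts),
            all(c("cohort_id", "n_tumor", "n_control") %in% names(cohorts)))
  if (any(cohorts$n_tumor < 1L) || any(cohorts$n_control < 1L))
    stop("all cohort group sizes must be positive")
  if (abs(coexpr_loading) >= 1) stop("coexpr_loading must lie in (-1, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_up + n_down + coexpr_size + 1L > n_genes)
    stop("planted blocks exceed n_genes: infeasible specification")
  if (abs(sum(ihc$tumor_intensity) - 1) > 1e-8 ||
      abs(sum(ihc$control_intensity) - 1) > 1e-8 ||
      abs(sum(ihc$tumor_proportion) - 1) > 1e-8 ||
      abs(sum(ihc$control_proportion) - 1) > 1e-8)
    stop("IHC multinomial probabilities must each sum to 1")
  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 n_genes = as.integer(n_genes), target = toupper(target),
                 target_smd = target_smd, n_up = as.integer(n_up),
                 n_down = as.integer(n_down), de_delta = de_delta,
                 coexpr_size = as.integer(coexpr_size),
                 coexpr_loading = coexpr_loading,
                 batch_shift_sd = batch_shift_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 stage_delta = stage_delta,
                 survival = survival, ihc = ihc),
            class = "simulation_spec")
}

#' Simulate a multi-cohort expression study with known ground truth
#'
#' Each value is `baseline_g + batch_shift_gc + delta_g 1(tumor) +
#' loading_g latent_s + N(0, noise_sd^2)` on the log2 scale. The target
#' gene's tumor shift is `target_smd * sqrt(loading^2 + noise_sd^2)`, so
#' its true per-cohort SMD equals `target_smd`; the co-expression block
#' shares a per-sample standard-normal latent factor with the target, so
#' the true all-sample correlation between a block gene and the target
#' (at `target_smd = 0`) is `loading^2 / (loading^2 + noise_sd^2)`.
#' Per-sample covariates (age, sex, stage for tumors) are drawn too.
#'
#' @param spec A [simulation_spec()].
#' @return List `cohorts` (list of [expression_cohort()]s) and `truth`
#'   (list `target`, `deg` data.frame, `ceg` data.frame, `true_r`).
#' @export
simulate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n_other <- spec$n_genes - 1L
  genes <- c(spec$target, sprintf("G%04d", seq_len(n_other)))
  up_genes <- genes[1L + seq_len(spec$n_up)]
  down_genes <- genes[1L + spec$n_up + seq_len(spec$n_down)]
  coexpr_genes <- genes[1L + spec$n_up + spec$n_down + seq_len(spec$coexpr_size)]

  lam <- spec$coexpr_loading
  sigma <- spec$noise_sd
  delta <- stats::setNames(numeric(spec$n_genes), genes)
  delta[up_genes] <- spec$de_delta
  delta[down_genes] <- -spec$de_delta
  delta[spec$target] <- spec$target_smd * sqrt(lam^2 + sigma^2)
  loading <- stats::setNames(numeric(spec$n_genes), genes)
  loading[c(spec$target, coexpr_genes)] <- lam
  baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)

  cohorts <- vector("list", nrow(spec$cohorts))
  for (ci in seq_len(nrow(spec$cohorts))) {
    row <- spec$cohorts[ci, ]
    n1 <- row$n_tumor; n0 <- row$n_control; n <- n1 + n0
    group <- c(rep("tumor", n1), rep("control", n0))
    shift <- stats::rnorm(spec$n_genes, 0, spec$batch_shift_sd)
    latent <- stats::rnorm(n)
    stage <- ifelse(group == "tumor",
                    sample(c("I", "II", "III", "IV"), n, replace = TRUE),
                    NA_character_)
    mat <- baseline + shift +
      outer(delta, as.numeric(group == "tumor")) +
      outer(loading, latent) +
      matrix(stats::rnorm(spec$n_genes * n, 0, sigma), spec$n_genes, n)
    if (spec$stage_delta != 0) {
      late <- which(!is.na(stage) & stage %in% c("III", "IV"))
      mat[spec$target, late] <- mat[spec$target, late] + spec$stage_delta
    }
    sample_ids <- sprintf("%s_s%03d", row$cohort_id, seq_len(n))
    dimnames(mat) <- list(genes, sample_ids)
    covariates <- data.frame(
      age = pmin(pmax(round(stats::rnorm(n, 52, 12)), 18), 85),
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.7, 0.3)),
      stage = stage,
      time = NA_real_, event = NA_integer_,
      row.names = sample_ids, stringsAsFactors = FALSE)
    platform <- if ("platform_id" %in% names(row)) row$platform_id else row$cohort_id
    cohorts[[ci]] <- expression_cohort(mat, group, row$cohort_id, platform,
                                       covariates = covariates,
                                       is_log_scale = TRUE)
  }
  names(cohorts) <- spec$cohorts$cohort_id
  true_r <- lam^2 / (lam^2 + sigma^2)
  list(cohorts = cohorts,
       truth = list(
         target = spec$target,
         target_smd = spec$target_smd,
         deg = data.frame(gene = c(up_genes, down_genes),
                          direction = rep(c("up", "down"),
                                          c(spec$n_up, spec$n_down)),
                          delta = delta[c(up_genes, down_genes)],
                          row.names = NULL, stringsAsFactors = FALSE),
         ceg = data.frame(gene = coexpr_genes,
                          loading = rep(lam, length(coexpr_genes)),
                          true_r = rep(true_r, length(coexpr_genes)),
                          row.names = NULL, stringsAsFactors = FALSE),
         true_r = true_r))
}

#' Simulate immunohistochemistry scoring records
#'
#' Every specimen receives `n_fields` fields whose intensity and proportion
#' scores are drawn independently from group-specific multinomials; the
#' specimen IRS is the mean per-field product.
#'
#' @param spec A [simulation_spec()].
#' @return data.frame `specimen_id`, `group`, `irs`, plus the raw per-field
#'   scores in attribute `"fields"` (long data.frame `specimen_id`,
#'   `intensity`, `proportion_category`).
#' @export
simulate_ihc <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  p <- spec$ihc
  one_group <- function(n, grp, int_p, prop_p) {
    ids <- sprintf("%s_%03d", grp, seq_len(n))
    fields <- data.frame(
      specimen_id = rep(ids, each = p$n_fields),
      intensity = sample(0:3, n * p$n_fields, replace = TRUE, prob = int_p),
      proportion_category = sample(0:4, n * p$n_fields, replace = TRUE, prob = prop_p),
      stringsAsFactors = FALSE)
    score <- tapply(irs(fields$intensity, fields$proportion_category),
                    fields$specimen_id, mean)
    list(records = data.frame(specimen_id = ids, group = grp,
                              irs = as.numeric(score[ids]),
                              stringsAsFactors = FALSE),
         fields = fields)
  }
  tu <- one_group(p$n_tumor, "tumor", p$tumor_intensity, p$tumor_proportion)
  co <- one_group(p$n_control, "control", p$control_intensity, p$control_proportion)
  out <- rbind(tu$records, co$records)
  attr(out, "fields") <- rbind(tu$fields, co$fields)
  out
}

#' Simulate survival outcomes driven by target-gene expression
#'
#' Event times are exponential with hazard `baseline_hazard`, multiplied by
#' `hr` for samples at or above the median of `expression`; censoring is an
#' independent exponential at `censor_rate` (rate 0 means no censoring).
#'
#' @param spec A [simulation_spec()].
#' @param expression Target-gene expression, one value per subject.
#' @return data.frame `time` (months), `event` (1 observed, 0 censored),
#'   `high` (logical, above-median marker).
#' @export
simulate_survival <- function(spec, expression) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 2L)
  sv <- spec$survival
  if (sv$baseline_hazard <= 0 || sv$hr <= 0) stop("hazards must be positive")
  n <- length(expression)
  high <- expression >= stats::median(expression)
  rate <- sv$baseline_hazard * ifelse(high, sv$hr, 1)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (sv$censor_rate > 0) stats::rexp(n, sv$censor_rate) else rep(Inf, n)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             high = high)
}
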