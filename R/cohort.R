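#' Construct an expression cohort
#'
#' An `expression_cohort` bundles one cohort's genes x samples expression
#' matrix with its per-sample tumor/control labels and optional clinical
#' covariates. All statistics in the package consume this container.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param group Character vector, one of `"tumor"`/`"control"` per sample,
#'   in column order.
#' @param cohort_id Cohort label (e.g. a platform or accession-style id).
#' @param platform_id Platform label; cohorts sharing a platform may be
#'   merged with [merge_same_platform()].
#' @param covariates Optional data.frame of per-sample covariates in column
#'   order; recognised columns are `age` (years), `sex` (`male`/`female`),
#'   `stage` (`I`..`IV`), `time` (survival months) and `event` (0/1).
#' @param is_log_scale Logical; `TRUE` when the matrix is already on the
#'   log2 scale.
#' @param batch Optional per-sample batch labels (defaults to `cohort_id`),
#'   retained by [merge_same_platform()] so batch structure survives merging.
#'
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(matrix, group, cohort_id,
                              platform_id = cohort_id,
                              covariates = NULL,
                              is_log_scale = FALSE,
                              batch = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must carry gene symbols as rownames and sample ids as colnames")
  rownames(matrix) <- toupper(rownames(matrix))
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene symbols; collapse them first (see collapse_duplicate_genes)")
  group <- as.character(group)
  if (length(group) != ncol(matrix))
    stop("`group` must have one label per sample")
  if (!all(group %in% c("tumor", "control")))
    stop("`group` labels must be 'tumor' or 'control'")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(matrix))
      stop("`covariates` must have one row per sample")
  }
  if (is.null(batch)) batch <- rep(cohort_id, ncol(matrix))
  if (length(batch) != ncol(matrix))
    stop("`batch` must have one label per sample")
  structure(
    list(cohort_id = as.character(cohort_id),
         platform_id = as.character(platform_id),
         matrix = matrix,
         group = group,
         covariates = covariates,
         is_log_scale = isTRUE(is_log_scale),
         batch = as.character(batch)),
    class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort '%s' (platform %s): %d genes x %d samples (%d tumor / %d control)%s\n",
              x$cohort_id, x$platform_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$group == "tumor"), sum(x$group == "control"),
              if (x$is_log_scale) ", log2 scale" else ""))
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$matrix)

#' Collapse duplicate gene symbols by averaging their rows
#'
#' Symbols are compared after uppercasing. The operation is idempotent.
#'
#' @param matrix Numeric matrix with gene symbols as rownames.
#' @return Matrix with unique, uppercased rownames.
#' @export
collapse_duplicate_genes <- function(matrix) {
  rn <- toupper(rownames(matrix))
  if (!anyDuplicated(rn)) {
    rownames(matrix) <- rn
    return(matrix)
  }
  keep <- unique(rn)
  out <- matrix(NA_real_, nrow = length(keep), ncol = ncol(matrix),
                dimnames = list(keep, colnames(matrix)))
  for (g in keep) {
    idx <- which(rn == g)
    out[g, ] <- if (length(idx) == 1L) matrix[idx, ] else colMeans(matrix[idx, , drop = FALSE])
  }
  out
}

#' Read an expression cohort from TSV/CSV plus a sample sheet
#'
#' The expression file has gene symbols in the first column and one column
#' per sample. The sample sheet is a TSV with at least `sample_id` and
#' `group` columns (plus optional `age`, `sex`, `stage`, `time`, `event`).
#' Duplicate gene symbols are collapsed by their arithmetic mean and all
#' symbols uppercased.
#'
#' @param path Expression matrix file; `.csv` is comma-separated, anything
#'   else tab-separated.
#' @param sample_sheet Path to the sample-sheet TSV.
#' @param cohort_id,platform_id Cohort metadata.
#' @param is_log_scale Whether values are already log2 scale.
#' @return An [expression_cohort()].
#' @export
read_expression_cohort <- function(path, sample_sheet, cohort_id,
                                   platform_id = cohort_id,
                                   is_log_scale = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus >=1 sample column")
  genes <- raw[[1L]]
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat), dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !(toupper(mat) %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value '%s' at gene %s, sample %s",
                 mat[bad[1, 1], bad[1, 2]], genes[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  rownames(num) <- genes
  num <- collapse_duplicate_genes(num)

  sheet <- utils::read.table(sample_sheet, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet must contain 'sample_id' and 'group' columns")
  missing <- setdiff(colnames(num), sheet$sample_id)
  if (length(missing))
    stop(sprintf("sample(s) absent from sample sheet: %s",
                 paste(missing, collapse = ", ")))
  sheet <- sheet[match(colnames(num), sheet$sample_id), , drop = FALSE]
  cov_cols <- intersect(c("age", "sex", "stage", "time", "event"), names(sheet))
  covariates <- if (length(cov_cols)) sheet[, cov_cols, drop = FALSE] else NULL
  if (!is.null(covariates)) rownames(covariates) <- sheet$sample_id
  expression_cohort(num, sheet$group, cohort_id, platform_id,
                    covariates = covariates, is_log_scale = is_log_scale)
}

#' Write an expression cohort back to TSV (matrix + sample sheet)
#'
#' @param cohort An [expression_cohort()].
#' @param path Output path for the expression TSV.
#' @param sample_sheet Output path for the sample-sheet TSV.
#' @return Invisibly, the paths written.
#' @export
write_expression_cohort <- function(cohort, path, sample_sheet) {
  df <- data.frame(gene = rownames(cohort$matrix), cohort$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = colnames(cohort$matrix),
                      group = cohort$group, stringsAsFactors = FALSE)
  if (!is.null(cohort$covariates)) sheet <- cbind(sheet, cohort$covariates)
  utils::write.table(sheet, sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, sample_sheet))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' members. Member symbols are uppercased; sets left empty are dropped with
#' a warning.
#'
#' @param path GMT file path.
#' @return A named list of character vectors with a `description` attribute
#'   per element, class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("malformed GMT line %d: expected >=3 tab-separated fields", i))
    members <- unique(toupper(parts[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning(sprintf("GMT term '%s' (line %d) has no members; dropped", parts[1], i))
      next
    }
    s <- members
    attr(s, "description") <- parts[2]
    sets[[parts[1]]] <- s
  }
  structure(sets, class = "gene_set_collection")
}

#' Read a STRING-style interaction edge list
#'
#' Expects a TSV with columns `node1`, `node2`, `combined_score` (header
#' names containing these, case-insensitive, are accepted; otherwise the
#' first three columns are used). Scores may be on the 0-1 scale or the
#' STRING 0-1000 scale; any score > 1 triggers division of all scores by
#' 1000. Self-loops are removed and duplicate undirected pairs collapsed,
#' keeping the maximum score.
#'
#' @param path Edge-list TSV.
#' @param min_score Keep edges with score strictly greater than this.
#' @return data.frame (`node_a`, `node_b`, `score`), class `edge_list`.
#' @export
read_edge_list <- function(path, min_score = 0.4) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list needs >=3 columns: node1, node2, score")
  pick <- function(pat, default) {
    hit <- grep(pat, names(df), ignore.case = TRUE)
    if (length(hit)) hit[1] else default
  }
  a <- toupper(as.character(df[[pick("^node.?1$|^protein.?1$", 1L)]]))
  b <- toupper(as.character(df[[pick("^node.?2$|^protein.?2$", 2L)]]))
  s <- as.numeric(df[[pick("score", 3L)]])
  if (any(is.na(s))) stop("non-numeric interaction score in edge list")
  if (any(s > 1)) s <- s / 1000
  edges <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b), score = s,
                      stringsAsFactors = FALSE)
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  edges <- edges[edges$score > min_score, , drop = FALSE]
  if (nrow(edges)) {
    key <- paste(edges$node_a, edges$node_b, sep = "\r")
    ord <- order(key, -edges$score)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$node_a, edges$node_b, sep = "\r")), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    warning("no edges survive the score filter; returning an empty edge list")
  }
  class(edges) <- c("edge_list", "data.frame")
  edges
}

#' Per-group summary statistics for one gene in one cohort
#'
#' The atom of all meta-analysis in the package: tumor and control sample
#' sizes, means and (n-1 denominator) standard deviations.
#'
#' @param n1,mean1,sd1 Tumor group size, mean, SD.
#' @param n0,mean0,sd0 Control group size, mean, SD.
#' @param label Optional cohort/gene label.
#' @return A `group_summary` list. The element `usable` flags whether both
#'   groups have at least two samples, i.e. variance-based statistics
#'   (t tests, SMD) are defined.
#' @export
group_summary <- function(n1, mean1, sd1, n0, mean0, sd0, label = NA_character_) {
  if (any(c(n1, n0) < 1L)) stop("group sizes must be >= 1")
  sds <- c(sd1, sd0)
  if (any(sds[!is.na(sds)] < 0)) stop("standard deviations must be >= 0")
  structure(list(n1 = as.integer(n1), mean1 = mean1, sd1 = sd1,
                 n0 = as.integer(n0), mean0 = mean0, sd0 = sd0,
                 label = label, usable = n1 >= 2L && n0 >= 2L),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary%s: tumor %d (%.3g +/- %.3g) vs control %d (%.3g +/- %.3g)%s\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$n1, x$mean1, x$sd1, x$n0, x$mean0, x$sd0,
              if (x$usable) "" else " [unusable for t/SMD]"))
  invisible(x)
}
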