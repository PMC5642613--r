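#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene ids and whose
#' header row holds sample ids.  A GCT-style two-line preamble (a first line
#' starting with `#`) is tolerated and skipped.  Loading is strict: duplicate
#' ids, non-numeric cells and missing values are errors naming the offending
#' row/column — nothing is repaired silently.
#'
#' @param path path to the TSV file.
#' @param annotation_path optional CSV of per-sample annotations with a
#'   `sample_id` column; ids must match the matrix columns exactly.
#' @return [ExpressionMatrix()].
#' @export
read_expression_matrix <- function(path, annotation_path = NULL) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 2L else 0L
  df <- read.delim(path, header = TRUE, sep = "\t", skip = skip,
                   check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression file needs a gene id column plus >= 1 sample")
  gene_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric or missing value at gene '", gene_ids[bad[1, 1]],
         "', sample '", colnames(vals)[bad[1, 2]], "'")
  rownames(num) <- gene_ids
  samples <- if (!is.null(annotation_path))
    read.csv(annotation_path, stringsAsFactors = FALSE) else NULL
  ExpressionMatrix(num, samples)
}

#' Write an expression matrix (and optional annotations) to disk
#'
#' Inverse of [read_expression_matrix()]: values at full precision (15
#' significant digits) so a write/read round trip is an identity.
#'
#' @param em [ExpressionMatrix()].
#' @param path TSV output path.
#' @param annotation_path optional CSV output path for the sample table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, annotation_path = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(em$values),
                   format(em$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    if (is.null(em$samples)) stop("matrix carries no sample annotations")
    write.csv(em$samples, annotation_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a survival table
#'
#' CSV with columns `patient_id`, `time_months`, `event` (0 = censored,
#' 1 = death observed) and optionally `group` (`"high"`/`"low"`).
#'
#' @param path CSV path.
#' @return `data.frame` of survival records.
#' @export
read_survival_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  validate_survival(df)
  df
}

validate_survival <- function(df) {
  bad_t <- which(!is.finite(df$time_months) | df$time_months < 0)
  if (length(bad_t))
    stop("negative or non-finite time for patient '",
         df$patient_id[bad_t[1]], "'")
  bad_e <- which(!df$event %in% c(0, 1))
  if (length(bad_e))
    stop("event code must be 0 or 1; patient '", df$patient_id[bad_e[1]],
         "' has '", df$event[bad_e[1]], "'")
  if ("group" %in% names(df)) {
    ok <- df$group %in% c("high", "low") | is.na(df$group) | df$group == ""
    if (!all(ok))
      stop("group must be 'high' or 'low'; patient '",
           df$patient_id[which(!ok)[1]], "'")
  }
  invisible(df)
}

#' Read an immunohistochemistry count table
#'
#' CSV with columns `patient_id`, `marker`, `region` (one of `Tu`, `Im`,
#' `Sd`: tumor region, infiltrative margin, distant stroma), `count1`,
#' `count2`, `count3` (cells per high-power field in three randomly selected
#' areas), plus optional positivity flags (`kappa_positive`, `igm_positive`)
#' and clinical covariates.  The per-record `mean_count` (arithmetic mean of
#' the three field counts) is recomputed at load time.
#'
#' @param path CSV path.
#' @return `data.frame` of IHC count records with a `mean_count` column.
#' @export
read_ihc_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "marker", "region", "count1", "count2", "count3")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad_r <- which(!df$region %in% c("Tu", "Im", "Sd"))
  if (length(bad_r))
    stop("region must be one of Tu, Im, Sd; patient '",
         df$patient_id[bad_r[1]], "' has region '", df$region[bad_r[1]], "'")
  cnt <- as.matrix(df[, c("count1", "count2", "count3")])
  bad_c <- which(!is.finite(cnt) | cnt < 0, arr.ind = TRUE)
  if (nrow(bad_c))
    stop("negative or non-numeric count for patient '",
         df$patient_id[bad_c[1, 1]], "', field ", bad_c[1, 2])
  df$mean_count <- rowMeans(cnt)
  df
}

#' Read a run configuration from YAML
#'
#' Configuration files are plain YAML.  Unspecified fields fall back to the
#' defaults of [run_config()].
#'
#' @param path YAML path.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(run_config(), cfg)
  validate_run_config(out)
  out
}

#' Default run configuration
#'
#' @param cc_threshold absolute-correlation filter threshold; genes with at
#'   least one partner with `|CC|` strictly above it are retained (default
#'   0.8).
#' @param linkage agglomeration rule; only `"complete"` is supported.
#' @param k_search_range integer pair, candidate cluster counts.
#' @param alpha significance level for reported tests (default 0.05).
#' @param seed integer; all randomness flows from it.
#' @return configuration list.
#' @export
run_config <- function(cc_threshold = 0.8, linkage = "complete",
                       k_search_range = c(2L, 10L), alpha = 0.05,
                       seed = 1L) {
  cfg <- list(cc_threshold = cc_threshold, linkage = linkage,
              k_search_range = as.integer(k_search_range), alpha = alpha,
              seed = as.integer(seed))
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!(cfg$cc_threshold > 0 && cfg$cc_threshold < 1))
    stop("cc_threshold must lie in (0, 1)")
  if (!identical(cfg$linkage, "complete"))
    stop("only complete linkage is supported")
  k <- cfg$k_search_range
  if (length(k) != 2L || k[1] < 2L || k[2] < k[1])
    stop("k_search_range must be an increasing pair with minimum >= 2")
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must lie in (0, 1)")
  invisible(cfg)
}

#' Recompute cohort summary statistics from a printed count table
#'
#' Takes a table of published cohort counts (one row per cohort with its
#' size and any labelled subgroup counts) and recomputes the derived
#' quantities: total patients across cohorts, subgroup fractions and
#' percentages.  The shipped `cohort_counts.csv` fixture carries the counts
#' printed for the three cohorts analysed here (pan-cancer discovery,
#' expression validation, surgical resection/IHC).
#'
#' @param path CSV with columns `cohort`, `n`, and optional `subgroup`,
#'   `subgroup_n` rows.  Defaults to the shipped fixture.
#' @return list with `total_n`, and per subgroup `fraction` and
#'   `percent` (rounded to one decimal).
#' @export
summarize_cohorts <- function(path = system.file("extdata",
                                                 "cohort_counts.csv",
                                                 package = "coexsurv")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cohorts <- unique(df[, c("cohort", "n")])
  sub <- df[!is.na(df$subgroup) & df$subgroup != "", , drop = FALSE]
  res <- lapply(seq_len(nrow(sub)), function(i) {
    frac <- sub$subgroup_n[i] / sub$n[i]
    list(cohort = sub$cohort[i], subgroup = sub$subgroup[i],
         n = sub$subgroup_n[i], fraction = frac,
         percent = round(100 * frac, 1))
  })
  names(res) <- paste(sub$cohort, sub$subgroup, sep = ".")
  list(total_n = sum(cohorts$n), subgroups = res)
}
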