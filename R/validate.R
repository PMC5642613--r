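#' Restrict a cohort matrix to a module's genes
#'
#' Cut-set projection: keeps the intersection of the module gene set with
#' the matrix genes; the number of module genes absent from the cohort is
#' reported.
#'
#' @param em [ExpressionMatrix()].
#' @param module_genes character vector of module gene ids.
#' @return `ExpressionMatrix` restricted to the intersection.
#' @export
project_module <- function(em, module_genes) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  hit <- intersect(module_genes, rownames(em$values))
  if (!length(hit))
    stop("no module gene present in the cohort matrix")
  miss <- length(module_genes) - length(hit)
  message(length(hit), " of ", length(module_genes),
          " module genes present", if (miss) paste0(" (", miss, " missing)"))
  em_subset(em, genes = hit)
}

#' Group arrays by module expression via hierarchical clustering
#'
#' Complete-linkage clustering of arrays on Euclidean distance over the
#' (standardized) module-gene values, cut at `k = 2`; the cluster with the
#' larger mean module expression on the pre-standardization scale is
#' labelled `"high"`.
#'
#' @param std_em [ExpressionMatrix()] of standardized module-gene values
#'   (see [double_standardize()]).
#' @param raw_em optional matrix on the original scale used to decide which
#'   cluster is "high"; defaults to `std_em`.
#' @param k number of array groups (default 2).
#' @return `data.frame` of class `GroupAssignment`: `sample_id`, `group`,
#'   with `provenance = "cluster_derived"` and a `rule` attribute.
#' @export
group_arrays <- function(std_em, raw_em = NULL, k = 2L) {
  stopifnot(inherits(std_em, "ExpressionMatrix"))
  v <- std_em$values
  if (ncol(v) < 2L) stop("cannot group a single array")
  if (is.null(raw_em)) raw_em <- std_em
  tree <- hclust(dist(t(v)), method = "complete")
  grp <- cutree(tree, k = k)
  if (length(unique(grp)) < k) stop("empty cluster after cut")
  mod_mean <- colMeans(raw_em$values[, colnames(v), drop = FALSE])
  cl_mean <- tapply(mod_mean, grp, mean)
  ord <- order(-cl_mean)               # highest mean first
  lab <- rep("low", k); lab[ord[1]] <- "high"
  if (k > 2L) lab[ord[-1]] <- paste0("low_", seq_len(k - 1L))
  out <- data.frame(sample_id = colnames(v),
                    group = unname(lab[grp]), row.names = NULL)
  attr(out, "provenance") <- "cluster_derived"
  attr(out, "rule") <- paste("complete-linkage Euclidean clustering of",
                             "arrays over module genes, cut at k =", k,
                             "; higher-mean cluster labelled high")
  class(out) <- c("GroupAssignment", "data.frame")
  out
}

#' Tumor vs non-tumor differential-expression descriptors for one gene
#'
#' Welch two-sample t, Wilcoxon rank-sum, linear-scale fold change (values
#' are unlogged before the ratio of means) and its log2.
#'
#' @param em [ExpressionMatrix()] with a `tissue` annotation containing
#'   both `"tumor"` and `"non_tumor"` samples (>= 2 each).
#' @param gene gene id.
#' @param log_base base of the stored log-scale values (default 2).
#' @return list: `gene`, `t_stat`, `t_p`, `wilcox_stat`, `wilcox_p`, `fc`,
#'   `log_fc`, `direction` (`"up"`/`"down"`/`"flat"` in tumor).
#' @export
describe_differential_expression <- function(em, gene, log_base = 2) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$samples) || !"tissue" %in% names(em$samples))
    stop("matrix carries no tissue annotation")
  if (!gene %in% rownames(em$values)) stop("unknown gene: ", gene)
  x <- em$values[gene, em$samples$tissue == "tumor"]
  y <- em$values[gene, em$samples$tissue == "non_tumor"]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 samples in each tissue class")
  tt <- t.test(x, y)                   # Welch by default
  wt <- suppressWarnings(wilcox.test(x, y))
  fc <- mean(log_base^x) / mean(log_base^y)
  lfc <- log2(fc)
  list(gene = gene, t_stat = unname(tt$statistic), t_p = tt$p.value,
       wilcox_stat = unname(wt$statistic), wilcox_p = wt$p.value,
       fc = fc, log_fc = lfc,
       direction = if (lfc > 0) "up" else if (lfc < 0) "down" else "flat")
}

#' Module projection, array grouping and survival stratification
#'
#' Orchestrates the validation-cohort stages: quantile normalization over
#' platforms, projection to the module gene cut-set, gene-then-array double
#' standardization, hierarchical grouping of tumor arrays into high/low
#' module-expression groups, Kaplan-Meier curves, log-rank test and Cox
#' hazard ratio on the patient groups, plus per-gene tumor vs non-tumor
#' differential-expression descriptors.
#'
#' @param em cohort [ExpressionMatrix()] with `patient_id`, `tissue` and
#'   (if two platforms are present) `platform` annotations.
#' @param module_genes module gene ids to project.
#' @param survival survival `data.frame` covering all grouped patients.
#' @param groups optional precomputed `GroupAssignment` of patients
#'   (`patient_id`, `group`); when supplied the clustering step is skipped
#'   (used, e.g., to evaluate truth labels directly).
#' @param out_dir optional directory; when given, every intermediate table
#'   is written as CSV.
#' @param log_base base of the log-scale expression values (default 2).
#' @return list: `groups` (per patient), `km` (per-group [km_estimate()]
#'   curves), `logrank`, `hr` ([cox_hr()] result), `de_table`
#'   (per-gene descriptors), `projected_genes`.
#' @export
validate_module_survival <- function(em, module_genes, survival,
                                     groups = NULL, out_dir = NULL,
                                     log_base = 2) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$samples) ||
      !all(c("patient_id", "tissue") %in% names(em$samples)))
    stop("matrix needs patient_id and tissue annotations")
  qn <- quantile_normalize(em)
  proj <- project_module(qn, module_genes)
  if (is.null(groups)) {
    std <- double_standardize(proj)
    tum <- std$samples$tissue == "tumor"
    if (sum(tum) < 2L) stop("need >= 2 tumor arrays to group")
    ga <- group_arrays(em_subset(std, sample_keep = which(tum)),
                       raw_em = em_subset(proj, sample_keep = which(tum)))
    groups <- data.frame(
      patient_id = std$samples$patient_id[tum][
        match(ga$sample_id, std$samples$sample_id[tum])],
      group = ga$group)
    attr(groups, "provenance") <- "cluster_derived"
  }
  sv <- merge(survival, groups, by = "patient_id",
              suffixes = c("_true", ""))
  if (nrow(sv) < nrow(groups))
    stop("survival records do not cover all grouped patients")
  hi <- sv[sv$group == "high", ]
  lo <- sv[sv$group == "low", ]
  if (nrow(hi) == 0L || nrow(lo) == 0L)
    stop("both survival groups must be non-empty")
  res <- list(
    groups = groups,
    km = list(high = km_estimate(hi), low = km_estimate(lo)),
    logrank = logrank_test(hi, lo),
    hr = cox_hr(sv),
    de_table = do.call(rbind, lapply(rownames(proj$values), function(g)
      as.data.frame(describe_differential_expression(proj, g,
                                                     log_base = log_base)))),
    projected_genes = rownames(proj$values))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res$groups, file.path(out_dir, "groups.csv"),
              row.names = FALSE)
    write.csv(res$de_table, file.path(out_dir, "de_table.csv"),
              row.names = FALSE)
    write.csv(res$km$high, file.path(out_dir, "km_high.csv"),
              row.names = FALSE)
    write.csv(res$km$low, file.path(out_dir, "km_low.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(hr = res$hr$hr, ci_low = res$hr$ci_low,
           ci_high = res$hr$ci_high, logrank_p = res$logrank$p),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
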