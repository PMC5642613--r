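#' Expression matrix container
#'
#' Lightweight container for a gene-by-sample grid of log-scale expression
#' values together with per-sample annotations, in the spirit of limma's
#' `EList`.  Values must be a finite numeric matrix with unique, non-empty
#' row (gene) and column (sample) names; annotations, when present, carry
#' one row per sample in matrix column order.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames.  Values are assumed to be on a log scale already; no
#'   transformation is applied.
#' @param samples optional `data.frame` of per-sample annotations with a
#'   `sample_id` column matching `colnames(values)`.  Typical columns:
#'   `entity` (tumor entity label), `platform`, `tissue` (`"tumor"` or
#'   `"non_tumor"`), `patient_id`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `samples`.
#' @export
ExpressionMatrix <- function(values, samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene (row) and sample (column) names")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite value at gene '", rownames(values)[bad[1, 1]],
         "', sample '", colnames(values)[bad[1, 2]], "'")
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    if (!"sample_id" %in% names(samples))
      stop("`samples` must contain a sample_id column")
    miss <- setdiff(colnames(values), samples$sample_id)
    extra <- setdiff(samples$sample_id, colnames(values))
    if (length(miss) || length(extra))
      stop("annotation sample ids do not match matrix columns; missing: [",
           paste(miss, collapse = ", "), "], unmatched: [",
           paste(extra, collapse = ", "), "]")
    samples <- samples[match(colnames(values), samples$sample_id), ,
                       drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(values = values, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  if (!is.null(x$samples)) {
    ann <- setdiff(names(x$samples), "sample_id")
    if (length(ann)) cat("sample annotations:", paste(ann, collapse = ", "), "\n")
    if ("tissue" %in% names(x$samples)) {
      tb <- table(x$samples$tissue)
      cat("tissue:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Subset an expression matrix
#'
#' @param x `ExpressionMatrix`.
#' @param genes optional character vector of gene ids to keep (order kept).
#' @param sample_keep optional logical or character selector of samples.
#' @return `ExpressionMatrix` restricted to the selection.
#' @export
em_subset <- function(x, genes = NULL, sample_keep = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) == length(genes)) stop("no requested gene present")
    v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  }
  s <- x$samples
  if (!is.null(sample_keep)) {
    v <- v[, sample_keep, drop = FALSE]
    if (!is.null(s)) s <- s[match(colnames(v), s$sample_id), , drop = FALSE]
  }
  ExpressionMatrix(v, s)
}
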