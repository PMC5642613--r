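#' Z-score each array
#'
#' Standardizes every array (column) to mean 0 and sample (n-1) standard
#' deviation 1, the per-array transform applied to the discovery cohort
#' after probe summarization upstream.
#'
#' @param em [ExpressionMatrix()] with >= 2 genes per array.
#' @return transformed `ExpressionMatrix`.
#' @export
zscore_by_array <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  if (nrow(v) < 2L) stop("need >= 2 genes per array")
  sds <- apply(v, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance array: '", colnames(v)[which(sds == 0)[1]], "'")
  z <- scale(v)            # column-wise: center then divide by sample sd
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  ExpressionMatrix(z, em$samples)
}

#' Summarize probe-level rows to gene level
#'
#' Gene-centred values are the per-array arithmetic mean of all probes
#' annotated to the gene.  Unmapped probes are dropped (count reported via
#' `message`); mapping is many probes to one gene.
#'
#' @param em probe-level [ExpressionMatrix()] (rows are probe ids).
#' @param map `data.frame` with columns `probe_id`, `gene_id`.
#' @return gene-level `ExpressionMatrix`.
#' @export
summarize_genes <- function(em, map) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!all(c("probe_id", "gene_id") %in% names(map)))
    stop("map needs probe_id and gene_id columns")
  if (anyDuplicated(map$probe_id))
    stop("duplicate probe id in map: '",
         map$probe_id[duplicated(map$probe_id)][1], "'")
  keep <- intersect(rownames(em$values), map$probe_id)
  if (!length(keep)) stop("no probe of the matrix appears in the map")
  dropped <- nrow(em$values) - length(keep)
  if (dropped > 0) message(dropped, " unmapped probe(s) dropped")
  v <- em$values[keep, , drop = FALSE]
  g <- map$gene_id[match(keep, map$probe_id)]
  sums <- rowsum(v, g)
  counts <- as.vector(table(g)[rownames(sums)])
  ExpressionMatrix(sums / counts, em$samples)
}

#' Quantile-normalize arrays
#'
#' Forces every array onto the common distribution given by the across-array
#' mean of sorted values; ranks within each array are preserved and ties
#' receive the mean reference value of their occupied ranks.  Used to align
#' the two array platforms of the validation cohort.  Idempotent.
#'
#' @param em [ExpressionMatrix()] with >= 2 arrays.
#' @return normalized `ExpressionMatrix`.
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 2L) stop("quantile normalization needs >= 2 arrays")
  v <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(v) <- dimnames(em$values)
  ExpressionMatrix(v, em$samples)
}

#' Gene-then-array double standardization
#'
#' Pass 1 centers and scales every gene row (mean 0, sample sd 1); pass 2
#' then centers and scales every array column.  The output satisfies the
#' column contract exactly; the row contract is generally broken by pass 2
#' and is not asserted.  This is the standardization applied to the
#' module-projected validation matrix before array grouping.
#'
#' @param em [ExpressionMatrix()].
#' @return standardized `ExpressionMatrix`.
#' @export
double_standardize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  rsd <- apply(v, 1L, sd)
  if (any(is.na(rsd) | rsd == 0))
    stop("zero-variance gene row: '",
         rownames(v)[which(is.na(rsd) | rsd == 0)[1]], "'")
  v <- (v - rowMeans(v)) / rsd
  csd <- apply(v, 2L, sd)
  if (any(is.na(csd) | csd == 0))
    stop("zero-variance array after gene standardization: '",
         colnames(v)[which(is.na(csd) | csd == 0)[1]], "'")
  v <- scale(v)
  attr(v, "scaled:center") <- attr(v, "scaled:scale") <- NULL
  ExpressionMatrix(v, em$samples)
}
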