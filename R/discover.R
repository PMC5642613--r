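#' Pairwise Pearson correlation between genes
#'
#' @param em [ExpressionMatrix()] with >= 3 samples and no constant gene.
#' @return symmetric correlation matrix (class `CorrelationTable`) with unit
#'   diagonal.
#' @export
pairwise_correlation <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  if (ncol(v) < 3L) stop("need >= 3 samples for pairwise correlation")
  sds <- apply(v, 1L, sd)
  if (any(sds == 0))
    stop("constant gene: '", rownames(v)[which(sds == 0)[1]], "'")
  cc <- cor(t(v))
  diag(cc) <- 1
  class(cc) <- c("CorrelationTable", class(cc))
  cc
}

#' Filter genes by best absolute correlation
#'
#' Retains every gene that has at least one OTHER gene with `|CC|` strictly
#' greater than `threshold`.  Note the filter is per-gene-best-partner, not
#' per-pair, so modules built downstream may contain pairs below the
#' threshold.
#'
#' @param corr correlation matrix from [pairwise_correlation()].
#' @param threshold real in (0, 1); default 0.8.
#' @return character vector of retained gene ids (possibly empty).
#' @export
filter_correlated_genes <- function(corr, threshold = 0.8) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  a <- abs(unclass(corr))
  diag(a) <- -Inf
  keep <- rownames(a)[apply(a, 1L, max) > threshold]
  message(length(keep), " of ", nrow(a), " genes pass |CC| > ", threshold)
  keep
}

#' Correlation-to-distance transform
#'
#' `d(i, j) = 1 - |CC(i, j)|`, the dissimilarity clustered downstream.
#'
#' @param corr correlation matrix.
#' @return symmetric distance matrix in `[0, 1]` with zero diagonal (class
#'   `DistanceTable`).
#' @export
correlation_distance <- function(corr) {
  d <- 1 - abs(unclass(corr))
  diag(d) <- 0
  class(d) <- c("DistanceTable", class(d))
  d
}

#' Complete-linkage hierarchical clustering of a distance table
#'
#' @param dist_table symmetric distance matrix (e.g. from
#'   [correlation_distance()]).
#' @param linkage only `"complete"` is supported.
#' @return an `hclust` tree; cutting at k (see [stats::cutree()]) yields a
#'   k-cluster partition.
#' @export
hierarchical_cluster <- function(dist_table, linkage = "complete") {
  if (!identical(linkage, "complete"))
    stop("only complete linkage is supported")
  d <- unclass(dist_table)
  if (nrow(d) < 2L) stop("cannot cluster fewer than 2 items")
  if (any(!is.finite(d))) stop("non-finite distance")
  hclust(as.dist(d), method = "complete")
}

within_dispersion <- function(x, groups) {
  # total within-cluster sum of squared deviations from cluster centroids;
  # x: items (genes) in rows, features (samples) in columns
  sum(vapply(split(seq_len(nrow(x)), groups), function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2L, colMeans(xs))^2)
  }, numeric(1)))
}

c_index <- function(d, groups) {
  # Hubert-Levin: C = (S - Smin) / (Smax - Smin) over within-cluster pairs
  n <- nrow(d)
  pairs <- d[upper.tri(d)]
  within <- outer(groups, groups, "==")[upper.tri(d)]
  n_w <- sum(within)
  if (n_w == 0L) return(NA_real_)
  s <- sum(pairs[within])
  srt <- sort(pairs)
  s_min <- sum(srt[seq_len(n_w)])
  s_max <- sum(srt[seq.int(length(srt) - n_w + 1L, length(srt))])
  if (s_max == s_min) stop("C index undefined: all pairwise distances equal")
  (s - s_min) / (s_max - s_min)
}

#' Select the number of clusters by KL and C validity indices
#'
#' Computes, for each k in the search range, the Krzanowski-Lai index
#' `KL(k) = |DIFF(k) / DIFF(k+1)|` with
#' `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)` (W = total within-cluster
#' dispersion around centroids in the expression space, p = number of
#' features/samples), and the Hubert-Levin C index
#' `C = (S - Smin) / (Smax - Smin)` on the clustering distances.  KL is
#' maximized, C minimized.
#'
#' @param tree `hclust` tree from [hierarchical_cluster()].
#' @param dist_table the distance matrix the tree was built from.
#' @param em [ExpressionMatrix()] supplying the expression space for W
#'   (rows must cover the clustered items).
#' @param k_range integer pair; KL needs partitions at k-1 and k+1, so the
#'   range must fit within `[2, n-2]`.
#' @param select_by which index picks the returned `k` when they disagree:
#'   `"KL"` (default) or `"C"`.
#' @return list of class `ValidityProfile`: `profile` (data.frame k, W, KL,
#'   C), `k_kl`, `k_c`, `k` (the selected one), `select_by`.
#' @export
select_cluster_count <- function(tree, dist_table, em, k_range = c(2L, 10L),
                                 select_by = c("KL", "C")) {
  select_by <- match.arg(select_by)
  items <- tree$labels
  n <- length(items)
  k_lo <- max(2L, k_range[1]); k_hi <- min(n - 2L, k_range[2])
  if (k_hi < k_lo) stop("k range empty after clipping to [2, n-2]")
  x <- em$values[items, , drop = FALSE]
  p <- ncol(x)
  d <- unclass(dist_table)[items, items]
  ks_w <- seq.int(k_lo - 1L, k_hi + 1L)
  cuts <- cutree(tree, k = ks_w)
  w <- vapply(seq_along(ks_w), function(i) within_dispersion(x, cuts[, i]),
              numeric(1))
  names(w) <- ks_w
  ks <- seq.int(k_lo, k_hi)
  diff_k <- function(k) {
    (k - 1)^(2 / p) * w[as.character(k - 1)] - k^(2 / p) * w[as.character(k)]
  }
  kl <- vapply(ks, function(k) {
    dk1 <- diff_k(k + 1L)
    if (dk1 == 0) return(NA_real_)    # undefined, excluded from argmax
    abs(diff_k(k) / dk1)
  }, numeric(1))
  cidx <- vapply(seq_along(ks), function(i) {
    c_index(d, cuts[, i + 1L])
  }, numeric(1))
  prof <- data.frame(k = ks, W = unname(w[as.character(ks)]), KL = kl,
                     C = cidx)
  if (all(is.na(kl))) stop("KL undefined over the whole range")
  k_kl <- ks[which.max(kl)]
  k_c <- ks[which.min(cidx)]
  structure(list(profile = prof, k_kl = k_kl, k_c = k_c,
                 k = if (select_by == "KL") k_kl else k_c,
                 select_by = select_by),
            class = "ValidityProfile")
}

#' @export
print.ValidityProfile <- function(x, ...) {
  cat("Cluster-count validity profile (k in ",
      min(x$profile$k), "..", max(x$profile$k), ")\n", sep = "")
  cat("KL index selects k =", x$k_kl, "; C index selects k =", x$k_c, "\n")
  cat("selected:", x$k, "(by", paste0(x$select_by, ")"), "\n")
  invisible(x)
}

#' Extract gene modules at a given cluster count
#'
#' Cuts the tree at k and reports the modules indexed by decreasing size,
#' each with its within-module correlation range (min, max over pairs;
#' `NA` and flagged for singletons).
#'
#' @param tree `hclust` tree.
#' @param k number of modules.
#' @param corr the `CorrelationTable` the tree derives from.
#' @return list of class `ModuleSet`: `modules` (list of gene id vectors,
#'   largest first), `summary` (data.frame module, size, cc_min, cc_max).
#' @export
extract_modules <- function(tree, k, corr) {
  groups <- cutree(tree, k = k)
  mods <- split(names(groups), groups)
  mods <- mods[order(-vapply(mods, length, integer(1)))]
  names(mods) <- paste0("module_", seq_along(mods))
  cc <- unclass(corr)
  rng <- t(vapply(mods, function(g) {
    if (length(g) < 2L) return(c(NA_real_, NA_real_))
    sub <- cc[g, g][upper.tri(diag(length(g)))]
    range(sub)
  }, numeric(2)))
  structure(list(modules = mods,
                 summary = data.frame(module = names(mods),
                                      size = vapply(mods, length, integer(1)),
                                      cc_min = rng[, 1], cc_max = rng[, 2],
                                      row.names = NULL)),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat("ModuleSet with", length(x$modules), "modules\n")
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Within-module co-expression in one tumor entity
#'
#' Recomputes pairwise correlations of the module genes on the samples of a
#' single entity and summarizes them — the stability check used to ask
#' whether a pan-cancer module stays coherent in, e.g., HCC tissue.
#'
#' @param em [ExpressionMatrix()] with an `entity` sample annotation.
#' @param module_genes character vector of member gene ids.
#' @param entity entity label selecting the sample subset (>= 3 samples).
#' @return list: `cc_min`, `cc_median`, `cc_max` (signed pairwise CC),
#'   `abs_cc_median`, `n_samples`, `n_genes`.
#' @export
module_stability_in_subset <- function(em, module_genes, entity) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$samples) || !"entity" %in% names(em$samples))
    stop("matrix carries no entity annotation")
  keep <- which(em$samples$entity == entity)
  if (length(keep) < 3L)
    stop("entity '", entity, "' has ", length(keep), " sample(s); need >= 3")
  sub <- em_subset(em, genes = module_genes, sample_keep = keep)
  cc <- pairwise_correlation(sub)
  v <- unclass(cc)[upper.tri(cc)]
  list(cc_min = min(v), cc_median = median(v), cc_max = max(v),
       abs_cc_median = median(abs(v)),
       n_samples = length(keep), n_genes = nrow(sub$values))
}

#' Full module-discovery pipeline
#'
#' Chains the discovery stages: optional probe summarization, per-array
#' Z-score, pairwise correlation, `|CC| > threshold` gene filter, 1-|CC|
#' distance, complete-linkage clustering, KL/C cluster-count selection and
#' module extraction.
#'
#' @param em probe- or gene-level [ExpressionMatrix()].
#' @param map optional probe-to-gene map (see [summarize_genes()]).
#' @param cc_threshold filter threshold (default 0.8).
#' @param k_range candidate cluster counts (default `c(2, 10)`).
#' @param select_by cluster-count index, `"KL"` (default) or `"C"`.
#' @param zscore whether to Z-score arrays first (default `TRUE`).
#' @return list: `modules` (a `ModuleSet`), `validity` (a
#'   `ValidityProfile`), `filtered_genes`, `correlation` (filtered
#'   `CorrelationTable`).
#' @export
discover_modules <- function(em, map = NULL, cc_threshold = 0.8,
                             k_range = c(2L, 10L), select_by = "KL",
                             zscore = TRUE) {
  if (!is.null(map)) em <- summarize_genes(em, map)
  if (zscore) em <- zscore_by_array(em)
  corr <- pairwise_correlation(em)
  keep <- filter_correlated_genes(corr, cc_threshold)
  if (length(keep) < 4L)
    stop("only ", length(keep),
         " gene(s) pass the correlation filter; cannot cluster")
  corr_f <- corr[keep, keep]
  class(corr_f) <- class(corr)
  d <- correlation_distance(corr_f)
  tree <- hierarchical_cluster(d)
  emf <- em_subset(em, genes = keep)
  validity <- select_cluster_count(tree, d, emf, k_range = k_range,
                                   select_by = select_by)
  mods <- extract_modules(tree, validity$k, corr_f)
  list(modules = mods, validity = validity, filtered_genes = keep,
       correlation = corr_f)
}
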