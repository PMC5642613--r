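test_that("pairwise correlation matches the product-moment formula", {
  set.seed(3)
  em <- toy_em(matrix(rnorm(25), 5, 5))
  cc <- pairwise_correlation(em)
  # brute-force covariance formula
  brute <- matrix(1, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    x <- em$values[i, ]; y <- em$values[j, ]
    brute[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(unclass(cc), brute, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(diag(cc)), rep(1, 5))

  aff <- toy_em(rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 1,
                      c = -c(1, 2, 3, 4)))
  ca <- pairwise_correlation(aff)
  expect_equal(ca["a", "b"], 1)
  expect_equal(ca["a", "c"], -1)

  expect_error(pairwise_correlation(toy_em(rbind(a = c(1, 1, 1),
                                                 b = c(1, 2, 3)))), "a")
  expect_error(pairwise_correlation(toy_em(matrix(rnorm(4), 2, 2))),
               ">= 3 samples")
})

test_that("correlation filter keeps best-partner genes with strict threshold", {
  cc <- diag(4)
  dimnames(cc) <- list(letters[1:4], letters[1:4])
  cc["a", "b"] <- cc["b", "a"] <- 0.9
  cc["c", "d"] <- cc["d", "c"] <- 0.8   # exactly at the boundary
  cc["a", "c"] <- cc["c", "a"] <- 0.1
  expect_identical(suppressMessages(filter_correlated_genes(cc, 0.8)),
                   c("a", "b"))
  # negative correlations count through the absolute value
  cc["c", "d"] <- cc["d", "c"] <- -0.85
  expect_identical(suppressMessages(filter_correlated_genes(cc, 0.8)),
                   letters[1:4])
  expect_error(filter_correlated_genes(cc, 1.5), "threshold")
})

test_that("correlation distance is 1 - |CC| with zero diagonal", {
  cc <- rbind(c(1, 1, -1, 0), c(1, 1, 0.3, -0.4),
              c(-1, 0.3, 1, 0.8), c(0, -0.4, 0.8, 1))
  dimnames(cc) <- list(letters[1:4], letters[1:4])
  d <- correlation_distance(cc)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d["a", "b"], 0)       # CC = 1
  expect_equal(d["a", "c"], 0)       # CC = -1
  expect_equal(d["a", "d"], 1)       # CC = 0
  expect_equal(unclass(d), 1 - abs(unclass(cc)), ignore_attr = TRUE)
  expect_identical(unclass(d), t(unclass(d)))
})

test_that("complete-linkage tree equals the brute-force agglomerative oracle", {
  # two tight pairs far apart merge pairwise first
  d <- rbind(c(0, 0.05, 0.9, 0.95), c(0.05, 0, 0.92, 0.9),
             c(0.9, 0.92, 0, 0.04), c(0.95, 0.9, 0.04, 0))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tree <- hierarchical_cluster(d)
  expect_true(same_partition(cutree(tree, 2),
                             c(1, 1, 2, 2)))

  # oracle equivalence over all sizes 3..8, several random instances each
  set.seed(99)
  for (n in 3:8) {
    for (rep in 1:5) {
      x <- matrix(rnorm(n * 4), n)
      dm <- as.matrix(dist(x))
      dimnames(dm) <- list(sprintf("i%d", 1:n), sprintf("i%d", 1:n))
      tr <- hierarchical_cluster(dm)
      oracle <- oracle_complete_linkage(dm)
      for (k in 1:n)
        expect_true(same_partition(cutree(tr, k), oracle[[k]]),
                    label = sprintf("n=%d rep=%d k=%d", n, rep, k))
    }
  }

  expect_error(hierarchical_cluster(matrix(0, 1, 1,
                                           dimnames = list("a", "a"))),
               "fewer than 2")
  dbad <- d; dbad[1, 2] <- Inf
  expect_error(hierarchical_cluster(dbad), "non-finite")
  expect_error(hierarchical_cluster(d, linkage = "average"), "complete")
})

test_that("KL and C indices agree with independent reimplementations", {
  set.seed(41)
  # 5 items in 4-dimensional feature space, two obvious groups
  x <- rbind(matrix(rnorm(8, 0, 0.1), 2), matrix(rnorm(12, 5, 0.1), 3))
  rownames(x) <- sprintf("i%d", 1:5)
  colnames(x) <- sprintf("f%d", 1:4)
  dm <- as.matrix(dist(x))
  tree <- hierarchical_cluster(dm)
  em <- ExpressionMatrix(x)
  vp <- select_cluster_count(tree, dm, em, k_range = c(2, 3))

  # independent W via the pairwise-distance identity:
  # W(cluster) = sum_{i<j} ||x_i - x_j||^2 / |cluster|
  w_of <- function(groups) {
    sum(vapply(split(rownames(x), groups), function(ids) {
      if (length(ids) < 2) return(0)
      dd <- as.matrix(dist(x[ids, , drop = FALSE]))^2
      sum(dd[upper.tri(dd)]) / length(ids)
    }, numeric(1)))
  }
  p <- ncol(x)
  w <- vapply(1:4, function(k) w_of(cutree(tree, k)), numeric(1))
  diff_k <- function(k) (k - 1)^(2 / p) * w[k - 1] - k^(2 / p) * w[k]
  kl2 <- abs(diff_k(2) / diff_k(3))
  kl3 <- abs(diff_k(3) / diff_k(4))
  expect_equal(vp$profile$KL, c(kl2, kl3), tolerance = 1e-10)

  # independent C index
  c_of <- function(groups) {
    pr <- dm[upper.tri(dm)]
    within <- outer(groups, groups, "==")[upper.tri(dm)]
    nw <- sum(within)
    s <- sum(pr[within])
    (s - sum(sort(pr)[1:nw])) /
      (sum(rev(sort(pr))[1:nw]) - sum(sort(pr)[1:nw]))
  }
  expect_equal(vp$profile$C,
               c(c_of(cutree(tree, 2)), c_of(cutree(tree, 3))),
               tolerance = 1e-10)
  expect_true(all(vp$profile$C >= 0 & vp$profile$C <= 1))
  expect_identical(vp$k_kl, 2L)
  expect_identical(vp$k_c, 2L)
})

test_that("validity indices select the planted cluster count", {
  set.seed(13)
  hits <- 0L
  for (rep in 1:10) {
    x <- rbind(matrix(rnorm(60, 0, 0.3), 10),
               matrix(rnorm(72, 4, 0.3), 12))
    rownames(x) <- sprintf("i%02d", 1:22)
    colnames(x) <- sprintf("f%d", 1:6)
    dm <- as.matrix(dist(x))
    tree <- hierarchical_cluster(dm)
    vp <- select_cluster_count(tree, dm, ExpressionMatrix(x),
                               k_range = c(2, 6))
    hits <- hits + (vp$k_kl == 2L && vp$k_c == 2L)
  }
  expect_gte(hits, 9L)

  # degenerate: all points identical -> C undefined
  x0 <- matrix(1, 6, 3, dimnames = list(sprintf("i%d", 1:6),
                                        sprintf("f%d", 1:3)))
  d0 <- as.matrix(dist(x0))
  t0 <- hierarchical_cluster(d0 + 0)
  expect_error(select_cluster_count(t0, d0, ExpressionMatrix(x0),
                                    k_range = c(2, 3)),
               "C index undefined|KL undefined")
})

test_that("module extraction partitions genes and reports CC ranges", {
  em <- suppressMessages(zscore_by_array(generate_pancancer_cohort(seed = 6)))
  truth <- attr(generate_pancancer_cohort(seed = 6), "truth")
  corr <- pairwise_correlation(em)
  keep <- suppressMessages(filter_correlated_genes(corr, 0.8))
  corr_f <- corr[keep, keep]
  d <- correlation_distance(corr_f)
  tree <- hierarchical_cluster(d)
  ms <- extract_modules(tree, 2, corr_f)
  expect_identical(sort(unlist(ms$modules, use.names = FALSE)), sort(keep))
  expect_setequal(ms$modules$module_1,
                  truth$gene_id[truth$module == "planted_1"])
  expect_true(all(ms$summary$cc_min <= ms$summary$cc_max))
  expect_true(all(ms$summary$cc_min >= -1 & ms$summary$cc_max <= 1))

  # k = n gives singletons with flagged (NA) CC ranges
  sing <- extract_modules(tree, length(keep), corr_f)
  expect_true(all(is.na(sing$summary$cc_min)))
  expect_true(all(sing$summary$size == 1L))
})

test_that("discovery is invariant to gene input order", {
  em <- generate_pancancer_cohort(seed = 15)
  res1 <- suppressMessages(discover_modules(em))
  set.seed(1)
  perm <- sample(nrow(em$values))
  em2 <- ExpressionMatrix(em$values[perm, ], em$samples)
  res2 <- suppressMessages(discover_modules(em2))
  sets1 <- lapply(res1$modules$modules, sort)
  sets2 <- lapply(res2$modules$modules, sort)
  expect_identical(sets1[order(vapply(sets1, `[`, "", 1))],
                   sets2[order(vapply(sets2, `[`, "", 1))])
})

test_that("module stability within an entity recomputes subset correlations", {
  em <- generate_pancancer_cohort(seed = 23)
  truth <- attr(em, "truth")
  mod <- truth$gene_id[truth$module == "planted_1"]

  # identity subset: single-entity config makes the subset the full cohort
  cfg <- default_pancancer_config()
  cfg$entities <- list(ALL = cfg$n_samples)
  em_all <- generate_pancancer_cohort(cfg, seed = 23)
  st_all <- module_stability_in_subset(em_all, mod, "ALL")
  cc_full <- pairwise_correlation(em_subset(em_all, genes = mod))
  expect_equal(st_all$cc_median,
               median(cc_full[upper.tri(cc_full)]))
  expect_equal(st_all$n_samples, cfg$n_samples)

  # HCC-like entity keeps the module coherent above background
  st <- module_stability_in_subset(em, mod, "HCC")
  bg <- truth$gene_id[truth$module == "background"][1:60]
  cc_bg <- pairwise_correlation(
    em_subset(em, genes = bg,
              sample_keep = which(em$samples$entity == "HCC")))
  bg_q95 <- quantile(abs(cc_bg[upper.tri(cc_bg)]), 0.95)
  expect_gt(st$abs_cc_median, bg_q95)

  tiny <- default_pancancer_config()
  expect_error(module_stability_in_subset(em, mod, "NOPE"), ">= 3")
})
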