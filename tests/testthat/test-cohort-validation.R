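test_that("module projection keeps the gene cut-set and reports misses", {
  vc <- generate_validation_cohort(seed = 2)
  mg <- default_validation_config()$module_gene_ids
  expect_message(full <- project_module(vc$expression, mg), "42 of 42")
  expect_identical(nrow(full$values), 42L)

  # only 10 of 42 present in a reduced cohort
  keep <- c(mg[1:10], sprintf("VBG%03d", 1:50))
  reduced <- em_subset(vc$expression, genes = keep)
  expect_message(p10 <- project_module(reduced, mg), "10 of 42.*32 missing")
  expect_identical(nrow(p10$values), 10L)

  none <- em_subset(vc$expression, genes = sprintf("VBG%03d", 1:50))
  expect_error(project_module(none, mg), "no module gene")
})

test_that("array grouping splits a shifted block perfectly and is order-invariant", {
  # two identical arrays duplicated 50x with a shifted block
  set.seed(10)
  base <- rnorm(20)
  v <- matrix(rep(base, 100), 20, 100)
  v[1:8, 51:100] <- v[1:8, 51:100] + 3
  v <- v + matrix(rnorm(2000, sd = 0.05), 20, 100)
  dimnames(v) <- list(sprintf("g%d", 1:20), sprintf("s%03d", 1:100))
  em <- ExpressionMatrix(v)
  ga <- group_arrays(em)
  expect_identical(unname(table(ga$group)["high"]), 50L)
  expect_true(all(ga$group[51:100] == "high"))

  # invariance under sample order permutation
  perm <- sample(100)
  emp <- ExpressionMatrix(v[, perm])
  gap <- group_arrays(emp)
  m <- merge(ga, gap, by = "sample_id")
  expect_identical(m$group.x, m$group.y)

  expect_error(group_arrays(ExpressionMatrix(v[, 1, drop = FALSE])),
               "single array")
})

test_that("strong overexpression makes cluster groups recover the truth", {
  # strong effect on the retained cut-set; note the signal must stay partial
  # (a shift on ALL projected genes is a rank-one array effect that the
  # array-wise centering of the double standardization removes exactly)
  cfg <- default_validation_config()
  cfg$overexpression_effect <- 6
  cfg$module_factor_sd <- 0.3
  cfg$noise_sd <- 0.5
  agree <- vapply(1:5, function(s) {
    vc <- generate_validation_cohort(cfg, seed = s)
    res <- suppressMessages(
      validate_module_survival(vc$expression, cfg$module_gene_ids,
                               vc$survival))
    m <- merge(res$groups, vc$truth$patients, by = "patient_id")
    mean(m$group == m$true_group)
  }, numeric(1))
  expect_true(all(agree > 0.95))
})

test_that("differential-expression descriptors follow their definitions", {
  v <- rbind(gA = c(5, 6, 7, 8, 5, 6, 7, 8),
             gB = c(6, 7, 8, 9, 5, 6, 7, 8))
  colnames(v) <- sprintf("s%d", 1:8)
  ann <- data.frame(sample_id = colnames(v),
                    tissue = rep(c("tumor", "non_tumor"), each = 4))
  em <- ExpressionMatrix(v, ann)

  flat <- describe_differential_expression(em, "gA")
  expect_equal(flat$fc, 1)
  expect_equal(flat$log_fc, 0)
  expect_identical(flat$direction, "flat")

  # constant +1 shift on the log2 scale -> logFC exactly 1
  shift <- describe_differential_expression(em, "gB")
  expect_equal(shift$log_fc, 1, tolerance = 1e-12)
  expect_identical(shift$direction, "up")
  # FC / logFC consistency
  expect_equal(2^shift$log_fc, shift$fc, tolerance = 1e-12)

  # Welch statistic long-hand on a 4-vs-4 example
  x <- c(5.1, 6.3, 7.2, 8.4); y <- c(4.0, 5.5, 5.9, 6.1)
  v2 <- rbind(gC = c(x, y))
  colnames(v2) <- colnames(v)
  em2 <- ExpressionMatrix(v2, ann)
  de <- describe_differential_expression(em2, "gC")
  welch <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 4)
  expect_equal(de$t_stat, welch, tolerance = 1e-12)

  solo <- ExpressionMatrix(v, data.frame(sample_id = colnames(v),
                                         tissue = "tumor"))
  expect_error(describe_differential_expression(solo, "gA"), ">= 2 samples")
})

test_that("the validation pipeline recovers the configured hazard ratio", {
  vc <- generate_validation_cohort(seed = 11)
  cfg <- default_validation_config()
  truth_groups <- data.frame(patient_id = vc$truth$patients$patient_id,
                             group = vc$truth$patients$true_group)
  res <- suppressMessages(
    validate_module_survival(vc$expression, cfg$module_gene_ids,
                             vc$survival, groups = truth_groups))
  expect_lt(abs(res$hr$log_hr - log(cfg$true_hr)),
            2.5 * res$hr$se_log_hr)
  expect_identical(sort(res$projected_genes), sort(cfg$module_gene_ids))
  expect_identical(nrow(res$de_table), 42L)
  expect_equal(2^res$de_table$log_fc, res$de_table$fc, tolerance = 1e-12)

  # intermediates written to disk
  out <- withr::local_tempdir()
  suppressMessages(
    validate_module_survival(vc$expression, cfg$module_gene_ids,
                             vc$survival, groups = truth_groups,
                             out_dir = out))
  expect_true(all(file.exists(file.path(
    out, c("groups.csv", "de_table.csv", "km_high.csv", "km_low.csv",
           "summary.json")))))

  # cohort with no events errors in the survival stage
  sv0 <- vc$survival
  sv0$event <- 0L
  expect_error(suppressMessages(
    validate_module_survival(vc$expression, cfg$module_gene_ids, sv0,
                             groups = truth_groups)))
})

test_that("permuted group labels give a null log-rank p distribution", {
  vc <- generate_validation_cohort(seed = 8)
  sv <- vc$survival
  set.seed(55)
  ps <- replicate(100, {
    g <- sample(sv$group)
    logrank_test(sv[g == "high", ], sv[g == "low", ])$p
  })
  expect_lte(sum(ps < 0.05), 12)
  expect_gte(sum(ps < 0.5), 30)
})
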