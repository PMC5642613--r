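#' Region-stratified IHC count and survival analysis
#'
#' For each marker: per-region mean +/- SEM of the per-patient mean counts;
#' pairwise region comparisons (Im vs Tu, Im vs Sd, Tu vs Sd) by
#' Mann-Whitney (unpaired default; Wilcoxon signed-rank on the within-
#' patient pairs behind the `paired` flag); per-region mean-split high/low
#' dichotomization followed by a log-rank survival comparison; cross-marker
#' and cross-region Pearson correlations of mean counts; association of the
#' Im high/low status with binary clinical covariates by a 2x2 exact test;
#' and Kappa/IgM positivity fractions per region compared between Im-high
#' and Im-low patients (exact test).  Patients missing any region of an
#' analysed marker are excluded (reported via `message`).
#'
#' @param records IHC count `data.frame` (see [read_ihc_table()] /
#'   [generate_ihc_cohort()]).
#' @param survival survival `data.frame` (`patient_id`, `time_months`,
#'   `event`).
#' @param alpha significance level used for flagging (default 0.05).
#' @param paired use the paired signed-rank test for region comparisons.
#' @param link_marker marker whose Im region defines the high/low status
#'   used for covariate and positivity associations (default `"CD20"`).
#' @return nested report list, one element per marker (`region_summary`,
#'   `region_comparisons`, `survival_by_region`), plus `correlations`,
#'   `covariate_associations`, `positivity` and `n_patients`.
#' @export
ihc_region_analysis <- function(records, survival, alpha = 0.05,
                                paired = FALSE, link_marker = "CD20") {
  regions <- c("Tu", "Im", "Sd")
  markers <- unique(records$marker)
  if (!"mean_count" %in% names(records))
    records$mean_count <- rowMeans(records[, c("count1", "count2",
                                               "count3")])
  # per-patient x marker wide table of region means
  wide <- list()
  for (mk in markers) {
    sub <- records[records$marker == mk, ]
    w <- Reduce(function(a, b) merge(a, b, by = "patient_id"),
                lapply(regions, function(rg) {
                  s <- sub[sub$region == rg, c("patient_id", "mean_count")]
                  names(s)[2] <- rg
                  s
                }))
    complete <- w[stats::complete.cases(w), , drop = FALSE]
    if (nrow(complete) < nrow(unique(sub["patient_id"])))
      message(mk, ": ",
              nrow(unique(sub["patient_id"])) - nrow(complete),
              " patient(s) missing a region, excluded")
    wide[[mk]] <- complete
  }

  report <- list()
  for (mk in markers) {
    w <- wide[[mk]]
    summ <- do.call(rbind, lapply(regions, function(rg) {
      ms <- mean_sem(w[[rg]])
      data.frame(region = rg, mean = ms$mean, sem = ms$sem, n = ms$n)
    }))
    cmp_pairs <- list(c("Im", "Tu"), c("Im", "Sd"), c("Tu", "Sd"))
    comps <- do.call(rbind, lapply(cmp_pairs, function(pr) {
      if (paired) {
        wt <- suppressWarnings(wilcox.test(w[[pr[1]]], w[[pr[2]]],
                                           paired = TRUE))
        data.frame(comparison = paste(pr, collapse = "_vs_"),
                   statistic = unname(wt$statistic), p = wt$p.value,
                   test = "signed_rank")
      } else {
        mw <- mann_whitney(w[[pr[1]]], w[[pr[2]]])
        data.frame(comparison = paste(pr, collapse = "_vs_"),
                   statistic = mw$u, p = mw$p, test = "mann_whitney")
      }
    }))
    comps$significant <- comps$p < alpha
    surv_by <- lapply(regions, function(rg) {
      grp <- split_high_low(setNames(w[[rg]], w$patient_id))
      sv <- merge(survival, grp, by = "patient_id",
                  suffixes = c("_cohort", ""))
      hi <- sv[sv$group == "high", ]; lo <- sv[sv$group == "low", ]
      lr <- logrank_test(hi, lo)
      list(region = rg, n_high = nrow(hi), n_low = nrow(lo),
           logrank_chisq = lr$chisq, logrank_p = lr$p,
           km_high = km_estimate(hi), km_low = km_estimate(lo))
    })
    names(surv_by) <- regions
    report[[mk]] <- list(region_summary = summ,
                         region_comparisons = comps,
                         survival_by_region = surv_by)
  }

  # cross-marker / cross-region correlations of per-patient mean counts
  cor_rows <- list()
  if (length(markers) >= 2L) {
    for (i in seq_along(markers)[-length(markers)])
      for (j in seq.int(i + 1L, length(markers)))
        for (rg in regions) {
          m <- merge(wide[[markers[i]]][, c("patient_id", rg)],
                     wide[[markers[j]]][, c("patient_id", rg)],
                     by = "patient_id")
          pc <- pearson_correlation(m[[2]], m[[3]])
          cor_rows[[length(cor_rows) + 1L]] <- data.frame(
            pair = paste0(markers[i], "_", markers[j]), region = rg,
            r = pc$r, p = pc$p, n = pc$n)
        }
  }
  for (mk in markers) {
    w <- wide[[mk]]
    for (pr in list(c("Tu", "Im"), c("Tu", "Sd"), c("Im", "Sd"))) {
      pc <- pearson_correlation(w[[pr[1]]], w[[pr[2]]])
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        pair = mk, region = paste(pr, collapse = "_"),
        r = pc$r, p = pc$p, n = pc$n)
    }
  }
  correlations <- do.call(rbind, cor_rows)

  # Im-region status of the linking marker
  wlink <- wide[[link_marker]]
  im_grp <- split_high_low(setNames(wlink$Im, wlink$patient_id))
  im_high <- im_grp$patient_id[im_grp$group == "high"]

  covars <- intersect(c("gender", "bridging_therapy", "hepatitis_b",
                        "hepatitis_c", "cirrhosis"), names(records))
  pat_cov <- unique(records[records$marker == link_marker &
                              records$region == "Im",
                            c("patient_id", covars), drop = FALSE])
  cov_rows <- lapply(covars, function(cv) {
    val <- pat_cov[[cv]]
    if (is.character(val)) val <- val == sort(unique(val))[1]
    tab <- table(high = pat_cov$patient_id %in% im_high, val)
    if (!all(dim(tab) == c(2L, 2L)))
      return(data.frame(covariate = cv, p = NA_real_, odds_ratio = NA_real_))
    ft <- fisher.test(tab)
    data.frame(covariate = cv, p = ft$p.value,
               odds_ratio = unname(ft$estimate))
  })
  covariate_associations <- do.call(rbind, cov_rows)
  if (!is.null(covariate_associations))
    covariate_associations$significant <- covariate_associations$p < alpha

  positivity <- NULL
  if (all(c("kappa_positive", "igm_positive") %in% names(records))) {
    pos <- unique(records[, c("patient_id", "region", "kappa_positive",
                              "igm_positive")])
    pos$im_group <- ifelse(pos$patient_id %in% im_high, "high", "low")
    positivity <- do.call(rbind, lapply(regions, function(rg) {
      s <- pos[pos$region == rg, ]
      do.call(rbind, lapply(c("kappa_positive", "igm_positive"),
                            function(fl) {
        tab <- table(factor(s$im_group, c("high", "low")),
                     factor(s[[fl]], c(FALSE, TRUE)))
        frac <- prop.table(tab, 1)[, "TRUE"]
        p <- if (all(rowSums(tab) > 0)) fisher.test(tab)$p.value
             else NA_real_
        data.frame(region = rg, flag = sub("_positive", "", fl),
                   frac_high = unname(frac["high"]),
                   frac_low = unname(frac["low"]), p = p)
      }))
    }))
  }

  list(markers = report, correlations = correlations,
       covariate_associations = covariate_associations,
       positivity = positivity,
       n_patients = vapply(wide, nrow, integer(1)),
       alpha = alpha, link_marker = link_marker)
}
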