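read_fixture_config <- function(name) {
  yaml::read_yaml(system.file("extdata", name, package = "coexsurv"))
}

#' Shipped default generator configurations
#'
#' The default fixture configurations ship with the package as YAML and
#' mirror the cohort statistics the pipeline is built around: a 42-gene
#' planted module among 500 background genes over 300 samples (plus a
#' 21-gene companion module so the cluster-number search is well-posed);
#' a 242-patient two-platform validation cohort with true hazard ratio 1.5;
#' a 119-patient IHC cohort with per-region marker means/SEMs of
#' 8+-2 / 65+-5 / 25+-3 (CD20 Tu/Im/Sd) and 13+-3 / 62+-7 / 23+-3 (CD79a).
#'
#' @return configuration list for the corresponding generator.
#' @export
default_pancancer_config <- function() read_fixture_config("discovery_default.yaml")

#' @rdname default_pancancer_config
#' @export
default_validation_config <- function() {
  cfg <- read_fixture_config("validation_default.yaml")
  if (is.null(cfg$module_gene_ids))
    cfg$module_gene_ids <- sprintf("M1_G%02d", seq_len(42L))
  cfg
}

#' @rdname default_pancancer_config
#' @export
default_ihc_config <- function() read_fixture_config("ihc_default.yaml")

#' Generate a pan-cancer discovery cohort with planted modules
#'
#' Each planted module is driven by one shared latent factor per sample with
#' equal loadings: `gene = mu + noise_sd * (sqrt(cc) * factor +
#' sqrt(1 - cc) * eps)`, so the expected pairwise Pearson correlation of two
#' module genes is exactly `cc`.  Background genes are independent noise.
#' Output is bit-identical for a given seed.
#'
#' @param config list, see [default_pancancer_config()].
#' @param seed integer seed.
#' @return [ExpressionMatrix()] with `entity` sample annotations and a
#'   `truth` attribute (`data.frame` gene_id, module label or `"background"`).
#' @export
generate_pancancer_cohort <- function(config = default_pancancer_config(),
                                      seed = 1L) {
  sizes <- vapply(config$planted_modules, `[[`, numeric(1), "size")
  ccs <- vapply(config$planted_modules, `[[`, numeric(1), "within_cc")
  if (any(ccs <= 0 | ccs >= 1)) stop("within_cc must lie in (0, 1)")
  if (any(sizes < 2)) stop("module sizes must be >= 2")
  n <- config$n_samples
  ent <- unlist(config$entities)
  if (sum(ent) != n) stop("entities must partition the samples exactly: ",
                          sum(ent), " != ", n)
  g_total <- sum(sizes) + config$n_background_genes
  if (any(sizes > g_total)) stop("module size exceeds total gene count")
  gene_ids <- c(unlist(lapply(seq_along(sizes), function(m)
    sprintf("M%d_G%02d", m, seq_len(sizes[m])))),
    sprintf("BG%04d", seq_len(config$n_background_genes)))
  withr::with_seed(seed, {
    mu <- rnorm(g_total, config$gene_mean, config$gene_mean_sd)
    v <- matrix(NA_real_, g_total, n,
                dimnames = list(gene_ids, sprintf("S%03d", seq_len(n))))
    row <- 0L
    for (m in seq_along(sizes)) {
      f <- rnorm(n)
      load <- sqrt(ccs[m]); res <- sqrt(1 - ccs[m])
      for (i in seq_len(sizes[m])) {
        row <- row + 1L
        v[row, ] <- mu[row] +
          config$noise_sd * (load * f + res * rnorm(n))
      }
    }
    for (i in seq_len(config$n_background_genes)) {
      row <- row + 1L
      v[row, ] <- mu[row] + config$noise_sd * rnorm(n)
    }
  })
  samples <- data.frame(sample_id = colnames(v),
                        entity = rep(names(ent), ent))
  em <- ExpressionMatrix(v, samples)
  attr(em, "truth") <- data.frame(
    gene_id = gene_ids,
    module = c(rep(sprintf("planted_%d", seq_along(sizes)), sizes),
               rep("background", config$n_background_genes)))
  em
}

#' Generate a two-platform validation cohort with survival
#'
#' Paired tumor/non-tumor arrays for `n_patients`.  Of the module genes,
#' the first `retained_coregulated_count` stay co-regulated in tumor
#' samples (shared per-patient factor) and carry the overexpression shift
#' in the randomly chosen "high" patient subset; the remaining module genes
#' and all background genes are independent noise.  Arrays split over two
#' platforms with location/scale offsets.  Survival times are exponential
#' with hazard `baseline_hazard * true_hr` for the low group and
#' `baseline_hazard` for the high group, administratively censored at
#' `censor_time` months.
#'
#' @param config list, see [default_validation_config()].
#' @param seed integer seed.
#' @return list: `expression` ([ExpressionMatrix()] with `patient_id`,
#'   `tissue`, `platform` annotations), `survival` (`data.frame` with true
#'   `group`), `truth` (list with `patients` and `genes` tables).
#' @export
generate_validation_cohort <- function(config = default_validation_config(),
                                       seed = 1L) {
  mg <- config$module_gene_ids
  r <- config$retained_coregulated_count
  if (r > length(mg))
    stop("retained_coregulated_count exceeds module size")
  if (!(config$true_hr > 0)) stop("true_hr must be positive")
  if (!(config$high_fraction > 0 && config$high_fraction < 1))
    stop("high_fraction must lie in (0, 1)")
  n <- config$n_patients
  gene_ids <- c(mg, sprintf("VBG%03d", seq_len(config$n_background_genes)))
  retained <- mg[seq_len(r)]
  pid <- sprintf("P%03d", seq_len(n))
  plat <- names(config$platforms)
  withr::with_seed(seed, {
    high <- rep(FALSE, n)
    high[sample.int(n, round(config$high_fraction * n))] <- TRUE
    platform <- sample(rep(plat, length.out = n))
    mu <- rnorm(length(gene_ids), config$gene_mean, config$gene_mean_sd)
    names(mu) <- gene_ids
    f <- rnorm(n)                      # shared tumor factor per patient
    tum <- matrix(rnorm(length(gene_ids) * n, sd = config$noise_sd),
                  length(gene_ids), n, dimnames = list(gene_ids, NULL))
    nor <- matrix(rnorm(length(gene_ids) * n, sd = config$noise_sd),
                  length(gene_ids), n, dimnames = list(gene_ids, NULL))
    tum <- tum + mu
    nor <- nor + mu
    tum[retained, ] <- tum[retained, ] +
      rep(config$module_factor_sd * f +
            config$overexpression_effect * high, each = r)
    v <- cbind(tum, nor)
    colnames(v) <- c(paste0(pid, "_T"), paste0(pid, "_N"))
    arr_plat <- rep(platform, 2L)
    for (pl in plat) {
      off <- config$platforms[[pl]]
      sel <- arr_plat == pl
      v[, sel] <- off$shift + off$scale * v[, sel]
    }
    hazard <- config$baseline_hazard *
      ifelse(high, 1, config$true_hr)
    t_event <- rexp(n, rate = hazard)
    event <- as.integer(t_event <= config$censor_time)
    time <- pmin(t_event, config$censor_time)
  })
  samples <- data.frame(sample_id = colnames(v),
                        patient_id = rep(pid, 2L),
                        tissue = rep(c("tumor", "non_tumor"), each = n),
                        platform = rep(platform, 2L),
                        entity = "HCC")
  surv <- data.frame(patient_id = pid, time_months = time, event = event,
                     group = ifelse(high, "high", "low"))
  truth <- list(
    patients = data.frame(patient_id = pid,
                          true_group = ifelse(high, "high", "low"),
                          platform = platform),
    genes = data.frame(gene_id = gene_ids,
                       role = c(rep("retained", r),
                                rep("module_nonretained", length(mg) - r),
                                rep("background",
                                    config$n_background_genes))))
  list(expression = ExpressionMatrix(v, samples), survival = surv,
       truth = truth)
}

ihc_latent_draw <- function(family, n, m, latent_var) {
  if (family == "negative_binomial") {
    rgamma(n, shape = m^2 / latent_var, rate = m / latent_var)
  } else {                              # lognormal_poisson
    s2 <- log(1 + latent_var / m^2)
    rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
}

#' Generate an IHC resection cohort with counts, survival and positivity
#'
#' Per marker and region, each patient gets a latent field intensity drawn
#' from the configured count family (gamma for the negative-binomial
#' default, lognormal as fallback) and three Poisson field counts around
#' it; the latent variance is chosen so the per-patient mean of the three
#' counts has variance `(SEM * sqrt(n_patients))^2`, i.e. the cohort-mean
#' SEM matches the configured one.  Survival hazard depends on the
#' patient's high/low status for the linking marker's Im region (mean
#' split); Kappa/IgM positivity flags and a cirrhosis covariate are tied to
#' the same status.
#'
#' @param config list, see [default_ihc_config()].
#' @param seed integer seed.
#' @return list: `counts` (IHC record `data.frame`), `survival`
#'   (`data.frame` with `group` = Im status), `truth` (list: `im_group`
#'   assignment, `config`).
#' @export
generate_ihc_cohort <- function(config = default_ihc_config(), seed = 1L) {
  n <- config$n_patients
  fam <- match.arg(config$count_family,
                   c("negative_binomial", "lognormal_poisson"))
  pid <- sprintf("IHC%03d", seq_len(n))
  for (mk in names(config$markers)) {
    for (rg in names(config$markers[[mk]])) {
      p <- config$markers[[mk]][[rg]]
      if (p$mean < 0 || p$sem <= 0) stop("means must be >= 0, SEMs > 0")
      v <- (p$sem * sqrt(n))^2
      if (fam == "negative_binomial" && v <= p$mean)
        stop("sd^2 <= mean for ", mk, " ", rg,
             ": infeasible for the negative binomial; ",
             "use count_family 'lognormal_poisson'")
      if (v <= p$mean / 3)
        stop("configured dispersion below Poisson floor for ", mk, " ", rg)
    }
  }
  withr::with_seed(seed, {
    rows <- list()
    means <- list()
    for (mk in names(config$markers)) {
      for (rg in names(config$markers[[mk]])) {
        p <- config$markers[[mk]][[rg]]
        v <- (p$sem * sqrt(n))^2
        lam <- ihc_latent_draw(fam, n, p$mean, v - p$mean / 3)
        cnt <- matrix(rpois(3L * n, rep(lam, each = 3L)), ncol = 3L,
                      byrow = TRUE)
        rows[[paste(mk, rg)]] <- data.frame(
          patient_id = pid, marker = mk, region = rg,
          count1 = cnt[, 1], count2 = cnt[, 2], count3 = cnt[, 3],
          mean_count = rowMeans(cnt))
        means[[paste(mk, rg)]] <- setNames(rowMeans(cnt), pid)
      }
    }
    link <- config$survival_link
    grp <- split_high_low(means[[paste(link$marker, link$region)]])
    is_high <- setNames(grp$group == "high", grp$patient_id)[pid]
    hazard <- link$baseline_hazard * ifelse(is_high, link$hr_high, 1)
    t_event <- rexp(n, rate = hazard)
    event <- as.integer(t_event <= link$censor_time)
    time <- pmin(t_event, link$censor_time)
    pos <- config$positivity_link
    counts <- do.call(rbind, rows)
    row_grp <- ifelse(is_high[counts$patient_id], "high", "low")
    row_p <- mapply(function(g, rg) pos[[g]][[rg]], row_grp, counts$region)
    counts$kappa_positive <- rbinom(nrow(counts), 1L, row_p) == 1
    counts$igm_positive <- rbinom(nrow(counts), 1L, row_p) == 1
    cl <- config$covariate_link
    cov <- data.frame(
      patient_id = pid,
      gender = ifelse(rbinom(n, 1L, cl$p_female) == 1, "female", "male"),
      age = round(pmax(30, rnorm(n, cl$age_mean, cl$age_sd))),
      t_stage = sample(1:4, n, replace = TRUE,
                       prob = c(0.2, 0.4, 0.3, 0.1)),
      bridging_therapy = rbinom(n, 1L, cl$p_bridging) == 1,
      hepatitis_b = rbinom(n, 1L, cl$p_hep_b) == 1,
      hepatitis_c = rbinom(n, 1L, cl$p_hep_c) == 1,
      cirrhosis = rbinom(n, 1L, ifelse(is_high, cl$p_cirrhosis_high,
                                       cl$p_cirrhosis_low)) == 1)
    counts <- merge(counts, cov, by = "patient_id", sort = FALSE)
  })
  rownames(counts) <- NULL
  surv <- data.frame(patient_id = pid, time_months = time, event = event,
                     group = ifelse(is_high, "high", "low"))
  list(counts = counts, survival = surv,
       truth = list(im_group = grp, config = config))
}
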