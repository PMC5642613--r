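#' Kaplan-Meier product-limit estimate
#'
#' @param records survival `data.frame` with `time_months` and `event`
#'   columns (1 = death observed, 0 = censored).  At tied times, events are
#'   processed before censorings.
#' @return `data.frame` of class `KMCurve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (survival probability just after `time`), starting
#'   from the implicit S(0) = 1.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0L) stop("no survival records")
  validate_survival(records)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = records)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
            class = c("KMCurve", "data.frame"))
}

#' Two-group log-rank test
#'
#' Observed vs expected events summed over distinct event times; the
#' statistic is chi-square with 1 df under the null of equal hazards.
#'
#' @param a,b survival `data.frame`s for the two groups (both non-empty,
#'   >= 1 event overall).
#' @return list: `chisq`, `p`, `n` (per-group sizes), `observed`,
#'   `expected` (per-group event counts).
#' @export
logrank_test <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be non-empty")
  df <- rbind(data.frame(time_months = a$time_months, event = a$event,
                         g = "a"),
              data.frame(time_months = b$time_months, event = b$event,
                         g = "b"))
  if (sum(df$event) == 0L) stop("log-rank needs >= 1 event overall")
  sd_ <- survival::survdiff(survival::Surv(time_months, event) ~ g,
                            data = df)
  list(chisq = unname(sd_$chisq),
       p = pchisq(sd_$chisq, df = 1L, lower.tail = FALSE),
       n = as.vector(sd_$n), observed = as.vector(sd_$obs),
       expected = as.vector(sd_$exp))
}

#' Cox proportional-hazards hazard ratio for a binary group
#'
#' Partial-likelihood fit with Efron tie handling (Breslow by flag) and a
#' Wald 95% confidence interval on the log scale.  By convention the
#' reported HR is hazard(`exposed`) / hazard(reference); the default
#' `exposed = "low"` makes an HR above 1 mean that low module expression /
#' low infiltration carries the higher hazard.
#'
#' @param records survival `data.frame` with a `group` column holding
#'   exactly two labels; both groups need >= 1 event.
#' @param exposed group label whose hazard goes in the numerator (default
#'   `"low"`; falls back to the second sorted label if absent).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `HazardRatioEstimate`: `hr`, `ci_low`, `ci_high`,
#'   `log_hr`, `se_log_hr`, `p`, `n_events` (named per group).
#' @export
cox_hr <- function(records, exposed = "low", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!"group" %in% names(records)) stop("records need a group column")
  validate_survival(records)
  lev <- sort(unique(records$group))
  if (length(lev) != 2L) stop("group must have exactly two levels")
  if (!exposed %in% lev) exposed <- lev[2L]
  ev <- tapply(records$event, records$group, sum)
  if (any(ev == 0))
    stop("monotone likelihood: group '", names(ev)[ev == 0][1],
         "' has no events; hazard ratio diverges")
  x <- as.integer(records$group == exposed)
  fit <- survival::coxph(survival::Surv(records$time_months,
                                        records$event) ~ x,
                         ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  b <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(b) || !is.finite(se)) stop("Cox fit did not converge")
  z <- qnorm(0.975)
  structure(list(hr = exp(b), ci_low = exp(b - z * se),
                 ci_high = exp(b + z * se), log_hr = b, se_log_hr = se,
                 p = 2 * stats::pnorm(-abs(b / se)),
                 n_events = ev, exposed = exposed, ties = ties),
            class = "HazardRatioEstimate")
}

#' @export
print.HazardRatioEstimate <- function(x, ...) {
  cat(sprintf("HR %.3g (95%%CI %.3g-%.3g), %s vs others, %s ties, p = %.4g\n",
              x$hr, x$ci_low, x$ci_high, x$exposed, x$ties, x$p))
  invisible(x)
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector; `SEM = sd / sqrt(n)` with the sample sd.
#' @return list: `mean`, `sem` (`NA` with a flag when n = 1), `n`.
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no values")
  list(mean = mean(values),
       sem = if (n >= 2L) sd(values) / sqrt(n) else NA_real_,
       n = n, sem_defined = n >= 2L)
}

#' Mean-split high/low dichotomization
#'
#' Values strictly larger than the cohort mean are labelled `"high"`,
#' values smaller — and, by the package's declared boundary rule, values
#' exactly equal to the mean — `"low"`.
#'
#' @param values named numeric vector (names are patient ids), >= 2
#'   non-constant values.
#' @return `data.frame` of class `GroupAssignment`: `patient_id`, `group`,
#'   with attributes `provenance = "mean_split"`, `rule`, `threshold`.
#' @export
split_high_low <- function(values) {
  if (is.null(names(values))) stop("values must be named by patient id")
  if (length(values) < 2L) stop("need >= 2 patients")
  if (max(values) == min(values))
    stop("all values equal; no mean split possible")
  m <- mean(values)
  out <- data.frame(patient_id = names(values),
                    group = ifelse(values > m, "high", "low"),
                    row.names = NULL)
  attr(out, "provenance") <- "mean_split"
  attr(out, "threshold") <- m
  attr(out, "rule") <- sprintf(
    "value > cohort mean (%.6g) -> high; <= mean -> low", m)
  class(out) <- c("GroupAssignment", "data.frame")
  out
}

#' Mann-Whitney rank-sum test
#'
#' Exact two-sided p by enumeration when the samples are tie-free and
#' `n_a * n_b <= 400`; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list: `u` (U statistic for `a` vs `b`), `p`, `exact` (logical).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  tie_free <- !anyDuplicated(c(a, b))
  use_exact <- tie_free && length(a) * length(b) <= 400
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need >= 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
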