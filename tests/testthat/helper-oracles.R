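# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths.

# Naive agglomerative complete linkage: rescans all cluster pairs at every
# step, merging the pair with the smallest maximum inter-point distance;
# ties go to the lexicographically smallest (i, j) pair.  Returns a list
# indexed by k (number of clusters) of membership vectors.
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  parts <- vector("list", n)
  parts[[n]] <- seq_len(n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    parts[[length(clusters)]] <- part
  }
  parts
}

# canonical labeling: clusters renumbered by first appearance
canon_partition <- function(g) match(g, unique(g))

same_partition <- function(a, b) {
  identical(canon_partition(as.integer(a)), canon_partition(as.integer(b)))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data only).
mw_enumeration_p <- function(a, b) {
  m <- length(a)
  vals <- c(a, b)
  u_obs <- sum(outer(a, b, ">"))
  idx <- utils::combn(length(vals), m)
  us <- apply(idx, 2L, function(ii) sum(outer(vals[ii], vals[-ii], ">")))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Two-group log-rank chi-square from the O/E/V sums written out long-hand.
logrank_chisq_oracle <- function(a, b) {
  time <- c(a$time_months, b$time_months)
  event <- c(a$event, b$event)
  grp <- rep(c(1L, 0L), c(nrow(a), nrow(b)))
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1L]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & grp == 1L)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & grp == 1L)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1L)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# small survival data.frame builder
surv_df <- function(time, event, id = sprintf("P%02d", seq_along(time)),
                    group = NULL) {
  df <- data.frame(patient_id = id, time_months = time, event = event)
  if (!is.null(group)) df$group <- group
  df
}

# exponential survival cohort with a binary group hazard ratio
sim_surv <- function(n_per_group, hr, baseline = 0.02, censor = 60) {
  n <- 2L * n_per_group
  grp <- rep(c("high", "low"), each = n_per_group)
  haz <- baseline * ifelse(grp == "low", hr, 1)
  t_ev <- rexp(n, haz)
  surv_df(pmin(t_ev, censor), as.integer(t_ev <= censor), group = grp)
}

# small deterministic expression matrix
toy_em <- function(values, genes = NULL, samples_df = NULL) {
  if (is.null(genes)) {
    genes <- rownames(values)
    if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  }
  rownames(values) <- genes
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  ExpressionMatrix(values, samples_df)
}
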