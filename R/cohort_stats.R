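# Organism-level quantification (median lifespan, relative lifespan, CFU)
# and the statistical tests used across the assays: one-way ANOVA with a
# Bonferroni post hoc (pooled-variance pairwise t), exact/approximate
# Mann-Whitney, and a per-timepoint two-way ANOVA for intensity curves.

test_result <- function(test, statistic, df, p_value, posthoc = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, posthoc = posthoc),
            class = "hq_test")
}

#' @export
print.hq_test <- function(x, ...) {
  cat(sprintf("<hq_test> %s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$test, x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Median lifespan summary per group
#'
#' Computes per-replicate median death days (midpoint convention for even
#' counts, i.e. the ordinary sample median) and summarizes each group as the
#' mean of its replicate medians with the SEM across replicates — the
#' "median +/- error" reporting style of replicate-tube survival assays.
#' With `by_replicate = FALSE` the pooled per-group median is returned
#' with no spread.
#'
#' @param cohort data.frame (group, replicate, individual_id, death_day),
#'   e.g. from [make_survival_cohort()].
#' @param by_replicate aggregate over replicate medians (default) or pool.
#' @return data.frame (group, n, n_replicates, median_days, sem_days) with
#'   attribute `replicate_medians`.
#' @export
median_lifespan <- function(cohort, by_replicate = TRUE) {
  if (nrow(cohort) == 0L) stop_hq("domain", "empty cohort")
  groups <- unique(cohort$group)
  rep_med <- do.call(rbind, lapply(groups, function(g) {
    sub <- cohort[cohort$group == g, ]
    if (nrow(sub) == 0L) stop_hq("domain", "empty group %s", g)
    do.call(rbind, lapply(unique(sub$replicate), function(r)
      data.frame(group = g, replicate = r,
                 median_days = stats::median(sub$death_day[sub$replicate == r]))))
  }))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- cohort[cohort$group == g, ]
    meds <- rep_med$median_days[rep_med$group == g]
    if (by_replicate) {
      data.frame(group = g, n = nrow(sub), n_replicates = length(meds),
                 median_days = mean(meds),
                 sem_days = if (length(meds) > 1) sem(meds) else NA_real_)
    } else {
      data.frame(group = g, n = nrow(sub), n_replicates = length(meds),
                 median_days = stats::median(sub$death_day), sem_days = NA_real_)
    }
  }))
  attr(out, "replicate_medians") <- rep_med
  out
}

#' Relative lifespan as a percentage of a reference
#'
#' @param group_median group median lifespan, days.
#' @param reference_median reference (e.g. wild-type) median lifespan, > 0.
#' @return 100 * group / reference (percent; rounding is left to display).
#' @export
relative_lifespan <- function(group_median, reference_median) {
  check_positive(reference_median, "reference median")
  if (any(group_median < 0)) stop_hq("domain", "medians must be >= 0")
  100 * group_median / reference_median
}

#' CFU per individual from a dilution series
#'
#' For each individual, the estimate is count x dilution factor at the
#' lowest countable dilution — the least-diluted spot whose count does not
#' exceed `saturation_limit` (confluent spots cannot be counted reliably).
#' When other dilutions were also plated, a consistency ratio (their naive
#' estimate divided by the chosen one) is reported. Individuals with all
#' spots saturated are flagged with `NA`.
#'
#' @param counts data.frame (individual_id, group, dilution, count, and
#'   optionally replicate/spot/age), e.g. from [make_dilution_counts()].
#' @param saturation_limit maximum countable colonies per spot.
#' @return data.frame (individual_id, group, cfu, dilution_used, saturated,
#'   consistency) — `consistency` is the mean ratio of non-chosen dilution
#'   estimates to the chosen estimate (NA when unique or cfu = 0).
#' @export
cfu_per_individual <- function(counts, saturation_limit = 150) {
  if (any(counts$count < 0) || any(counts$count != round(counts$count)))
    stop_hq("domain", "colony counts must be non-negative integers")
  key <- interaction(counts$group, counts$individual_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(counts, key), function(sub) {
    est <- sub$count * sub$dilution
    countable <- sub$count <= saturation_limit
    if (!any(countable)) {
      return(data.frame(individual_id = sub$individual_id[1],
                        group = sub$group[1], cfu = NA_real_,
                        dilution_used = NA_real_, saturated = TRUE,
                        consistency = NA_real_))
    }
    pick <- which(countable)[which.min(sub$dilution[countable])]
    cfu <- est[pick]
    others <- est[-pick]
    data.frame(individual_id = sub$individual_id[1], group = sub$group[1],
               cfu = cfu, dilution_used = sub$dilution[pick],
               saturated = FALSE,
               consistency = if (length(others) && cfu > 0)
                 mean(others / cfu) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way ANOVA across groups
#'
#' Classic fixed-effects one-way ANOVA: F = MS_between / MS_within on
#' (k - 1, N - k) degrees of freedom (delegated to
#' [stats::oneway.test()] with equal variances).
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   `group` and `value` columns.
#' @return `hq_test` with the F statistic, df and p-value.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L) stop_hq("domain", "need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop_hq("domain", "each group needs n >= 2")
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    stop_hq("undefined_f", "zero within-group variance in every group")
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups), lengths(groups))))
  ft <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  test_result("one-way ANOVA", unname(ft$statistic),
              unname(c(ft$parameter["num df"], ft$parameter["denom df"])),
              unname(ft$p.value))
}

#' Bonferroni post hoc comparisons
#'
#' Pairwise t tests using the pooled within-group variance of *all* groups
#' (df = N - k), with each raw p multiplied by the number of requested
#' comparisons and capped at 1 — the classic Bonferroni multiple-comparison
#' test that follows a one-way ANOVA.
#'
#' @param groups named list of numeric vectors or data.frame
#'   (group, value).
#' @param comparisons list of character pairs to test; `NULL` = all pairs.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame (group1, group2, t, df, p_raw, p_adj, significant).
#' @export
bonferroni_posthoc <- function(groups, comparisons = NULL, alpha = 0.05) {
  groups <- as_group_list(groups)
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2L, simplify = FALSE)
  }
  for (p in comparisons)
    if (!all(p %in% names(groups)))
      stop_hq("domain", "unknown group in comparison: %s", paste(p, collapse = " vs "))
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / (N - k)
  m <- length(comparisons)
  out <- do.call(rbind, lapply(comparisons, function(p) {
    g1 <- groups[[p[1]]]; g2 <- groups[[p[2]]]
    se <- sqrt(msw * (1 / length(g1) + 1 / length(g2)))
    t <- (mean(g1) - mean(g2)) / se
    praw <- 2 * stats::pt(-abs(t), df = N - k)
    data.frame(group1 = p[1], group2 = p[2], t = t, df = N - k,
               p_raw = praw, p_adj = min(1, m * praw),
               significant = min(1, m * praw) < alpha)
  }))
  rownames(out) <- NULL
  out
}

# U statistic for x vs y using midranks: U = #(x > y) + 0.5 #(x == y)
u_statistic <- function(rx_sum, n1, n2) rx_sum - n1 * (n1 + 1) / 2

#' Mann-Whitney U test
#'
#' Midrank tie handling. For small samples (both n <= 8) the p-value is
#' exact, from full enumeration of all C(n1+n2, n1) group assignments of
#' the pooled observations (valid under ties); otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Two-tailed p is the probability of a U at least as far from
#' n1*n2/2 as observed; the one-tailed alternative is "x tends larger
#' than y".
#'
#' @param x,y numeric samples.
#' @param tails `"two"` or `"one"`.
#' @param exact force exact enumeration (`TRUE`/`FALSE`); default chooses
#'   by sample size.
#' @return `hq_test` with the U statistic (for x) and p-value.
#' @export
mann_whitney <- function(x, y, tails = c("two", "one"), exact = NULL) {
  tails <- match.arg(tails)
  if (length(x) == 0L || length(y) == 0L)
    stop_hq("domain", "both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)   # midranks
  u <- u_statistic(sum(rk[seq_len(n1)]), n1, n2)
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- max(n1, n2) <= 8 || n1 + n2 <= 10
  if (exact) {
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2L, function(ix) u_statistic(sum(rk[ix]), n1, n2))
    p <- switch(tails,
                two = mean(abs(us - mu) >= abs(u - mu) - 1e-9),
                one = mean(us >= u - 1e-9))
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) { p <- 1 } else {
      if (tails == "two") {
        z <- (abs(u - mu) - 0.5) / sqrt(sig2)
        p <- min(1, 2 * stats::pnorm(-max(z, 0)))
      } else {
        z <- (u - mu - 0.5) / sqrt(sig2)
        p <- stats::pnorm(z, lower.tail = FALSE)
      }
    }
  }
  test_result(sprintf("Mann-Whitney (%s-tailed, %s)", tails,
                      if (exact) "exact" else "normal approximation"),
              u, c(n1, n2), p)
}

#' Two-way (group x time) ANOVA with per-timepoint Bonferroni comparisons
#'
#' Fits a fixed-effects two-factor ANOVA on the long-format curves and then
#' compares groups at each timepoint with the Bonferroni correction over
#' timepoints, reporting the earliest timepoint whose adjusted p falls
#' below `alpha` — the standard way of asking "from when do these curves
#' differ?".
#'
#' @param curves data.frame (subject, group, time, value); every subject
#'   must be sampled on the same time grid (no silent interpolation).
#' @param alpha significance level.
#' @return list with `main` (`hq_test` for the group effect, plus
#'   `interaction` row), `per_time` data.frame (time, F, df1, df2, p_raw,
#'   p_adj, significant) and `earliest_significant` (time or NA).
#' @export
timecourse_anova <- function(curves, alpha = 0.05) {
  needed <- c("subject", "group", "time", "value")
  if (!all(needed %in% names(curves)))
    stop_hq("domain", "curves need columns subject, group, time, value")
  grids <- split(curves$time, curves$subject)
  ref <- sort(unique(grids[[1]]))
  if (!all(vapply(grids, function(g) identical(sort(unique(g)), ref), logical(1))))
    stop_hq("domain", "subjects are on different time grids")
  if (min(table(unique(curves[, c("subject", "group")])$group)) < 2)
    stop_hq("domain", "need at least 2 subjects per group")

  curves$group <- factor(curves$group)
  curves$ftime <- factor(curves$time)
  times <- sort(unique(curves$time))
  if (length(times) > 1L) {
    fit <- stats::aov(value ~ group * ftime, data = curves)
    tab <- summary(fit)[[1]]
    rn <- trimws(rownames(tab))   # summary.aov pads row names
    g <- which(rn == "group"); gx <- which(rn == "group:ftime")
    rs <- which(rn == "Residuals")
    main <- test_result("two-way ANOVA (group)",
                        tab[g, "F value"],
                        c(tab[g, "Df"], tab[rs, "Df"]),
                        tab[g, "Pr(>F)"])
    main$interaction <- c(F = tab[gx, "F value"], p = tab[gx, "Pr(>F)"])
  } else {
    main <- one_way_anova(split(curves$value, curves$group))
  }

  m <- length(times)
  per_time <- do.call(rbind, lapply(times, function(tt) {
    sub <- curves[curves$time == tt, ]
    ft <- stats::oneway.test(value ~ group, data = sub, var.equal = TRUE)
    praw <- unname(ft$p.value)
    # degenerate timepoints (zero variance everywhere) are never significant
    padj <- if (is.finite(praw)) min(1, m * praw) else NA_real_
    data.frame(time = tt, F = unname(ft$statistic),
               df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
               p_raw = praw, p_adj = padj,
               significant = isTRUE(padj < alpha))
  }))
  sig <- per_time$time[per_time$significant]
  list(main = main, per_time = per_time,
       earliest_significant = if (length(sig)) min(sig) else NA_real_)
}
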