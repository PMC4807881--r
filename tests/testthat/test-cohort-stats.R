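cohort_of <- function(days, group = "g", replicate = 1) {
  data.frame(group = group, replicate = replicate,
             individual_id = seq_along(days), death_day = days)
}

test_that("median lifespan uses the midpoint convention and replicate structure", {
  expect_equal(median_lifespan(cohort_of(rep(23, 10)))$median_days, 23)
  expect_equal(median_lifespan(cohort_of(c(10, 20, 30)))$median_days, 20)
  expect_equal(median_lifespan(cohort_of(c(10, 20, 30, 40)))$median_days, 25)

  # group summary is the mean of replicate medians with SEM
  coh <- rbind(cohort_of(c(10, 20, 30), replicate = 1),
               cohort_of(c(30, 40, 50), replicate = 2))
  ml <- median_lifespan(coh)
  expect_equal(ml$median_days, 30)
  expect_equal(ml$sem_days, sd(c(20, 40)) / sqrt(2))
  expect_equal(ml$n_replicates, 2)
  empty <- data.frame(group = character(0), replicate = integer(0),
                      individual_id = integer(0), death_day = numeric(0))
  expect_error(median_lifespan(empty), class = "hq_domain_error")
})

test_that("relative lifespan reproduces the printed worked example", {
  expect_equal(relative_lifespan(23, 49), 100 * 23 / 49, tolerance = 1e-12)
  expect_equal(round(relative_lifespan(23, 49)), 47)
  expect_equal(relative_lifespan(40, 40), 100)
  expect_equal(relative_lifespan(38, 49), 77.55102, tolerance = 1e-5)
  expect_error(relative_lifespan(10, 0), class = "hq_domain_error")
})

test_that("CFU estimation picks the lowest countable dilution", {
  one <- data.frame(individual_id = 1, group = "g", dilution = 1, count = 0)
  expect_equal(cfu_per_individual(one)$cfu, 0)

  ten <- data.frame(individual_id = 1, group = "g", dilution = 10, count = 30)
  expect_equal(cfu_per_individual(ten)$cfu, 300)

  both <- data.frame(individual_id = 1, group = "g",
                     dilution = c(1, 10), count = c(200, 30))
  est <- cfu_per_individual(both)
  expect_equal(est$cfu, 300)            # 200 colonies exceed the spot ceiling
  expect_equal(est$dilution_used, 10)
  expect_equal(est$consistency, 200 / 300, tolerance = 1e-12)

  sat <- data.frame(individual_id = 1, group = "g",
                    dilution = c(1, 10), count = c(900, 400))
  expect_true(cfu_per_individual(sat)$saturated)
  expect_true(is.na(cfu_per_individual(sat)$cfu))
  expect_error(cfu_per_individual(data.frame(individual_id = 1, group = "g",
                                             dilution = 1, count = -2)),
               class = "hq_domain_error")
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  an <- one_way_anova(g)
  expect_equal(an$statistic, 3, tolerance = 1e-12)     # SSB = 6, SSW = 6
  expect_equal(an$df, c(2, 6))
  expect_equal(an$p_value, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  set.seed(13)
  x <- rnorm(8); y <- rnorm(9, 0.6)
  two <- one_way_anova(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(two$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(two$p_value, tt$p.value, tolerance = 1e-10)

  same <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 1)))
  expect_equal(same$statistic, 0)
  expect_error(one_way_anova(list(a = c(1, 1), b = c(2, 2))),
               class = "hq_undefined_f_error")
  expect_error(one_way_anova(list(a = 1:3)), class = "hq_domain_error")
})

test_that("Bonferroni post hoc multiplies raw p by the comparison count", {
  set.seed(3)
  g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2), d = rnorm(6))
  ph <- bonferroni_posthoc(g)       # all 6 pairs
  expect_equal(ph$p_adj, pmin(1, 6 * ph$p_raw), tolerance = 1e-12)
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_true(all(ph$p_adj <= 1))

  # single comparison: adjusted equals raw
  one <- bonferroni_posthoc(g, comparisons = list(c("a", "b")))
  expect_equal(one$p_adj, one$p_raw, tolerance = 1e-12)

  # cross-check raw p against base R pooled-sd pairwise t tests
  df <- data.frame(value = unlist(g), grp = rep(names(g), lengths(g)))
  base_p <- pairwise.t.test(df$value, df$grp, p.adjust.method = "none",
                            pool.sd = TRUE)$p.value
  expect_equal(ph$p_raw[ph$group1 == "a" & ph$group2 == "b"],
               base_p["b", "a"], tolerance = 1e-10)
  expect_equal(ph$p_raw[ph$group1 == "c" & ph$group2 == "d"],
               base_p["d", "c"], tolerance = 1e-10)

  expect_error(bonferroni_posthoc(g, comparisons = list(c("a", "zz"))),
               class = "hq_domain_error")
})

test_that("Mann-Whitney handles separation, symmetry and the enumeration oracle", {
  expect_equal(mann_whitney(c(1, 2, 3), c(5, 6, 7, 8))$statistic, 0)
  expect_equal(mann_whitney(c(2, 4, 6), c(2, 4, 6))$statistic, 4.5)  # n1 n2 / 2

  mw <- mann_whitney(c(1, 3), c(2, 4))
  expect_equal(mw$statistic, 1)
  expect_equal(mw$p_value, mw_enum_p(c(1, 3), c(2, 4)), tolerance = 1e-12)
  expect_equal(mw$p_value, 2 / 3, tolerance = 1e-12)

  set.seed(77)
  for (rep in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, mw_enum_p(x, y), tolerance = 1e-12)
    expect_equal(mann_whitney(x, y, tails = "one")$p_value,
                 mw_enum_p(x, y, "one"), tolerance = 1e-12)
  }

  # tie-free exact p agrees with wilcox.test
  set.seed(5)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(mann_whitney(x, y)$p_value, wilcox.test(x, y)$p.value,
               tolerance = 1e-10)
  # large samples fall back to the tie-corrected normal approximation
  xl <- rnorm(30); yl <- rnorm(25, 0.4)
  expect_equal(mann_whitney(xl, yl)$p_value,
               wilcox.test(xl, yl, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
  expect_error(mann_whitney(numeric(0), 1:3), class = "hq_domain_error")
})

test_that("timecourse ANOVA locates the divergence of group curves", {
  grid <- seq(0, 30, by = 3)
  make_curves <- function(shift_after, n = 6, noise = 2, seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(1:(2 * n), function(s) {
      grp <- if (s <= n) "wt" else "mut"
      mu <- ifelse(grid >= shift_after & grp == "mut", 25, 0)
      data.frame(subject = s, group = grp, time = grid,
                 value = mu + rnorm(length(grid), 0, noise))
    }))
  }
  div <- timecourse_anova(make_curves(15))
  expect_lt(div$main$p_value, 0.001)
  expect_gte(div$earliest_significant, 15)   # never before the changepoint
  expect_false(any(div$per_time$significant[div$per_time$time < 15]))

  flat <- make_curves(1e9)                    # identical distributions
  nothing <- timecourse_anova(flat)
  expect_true(is.na(nothing$earliest_significant))

  # identical deterministic curves: degenerate, never significant
  const <- expand.grid(subject = 1:4, time = grid)
  const$group <- ifelse(const$subject <= 2, "wt", "mut")
  const$value <- 5
  expect_true(is.na(timecourse_anova(const)$earliest_significant))

  one_t <- make_curves(0)[make_curves(0)$time == 0, ]
  red <- timecourse_anova(one_t)
  expect_equal(red$main$test, "one-way ANOVA")

  bad <- make_curves(15)
  bad <- bad[!(bad$subject == 1 & bad$time == 3), ]
  expect_error(timecourse_anova(bad), class = "hq_domain_error")
})
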