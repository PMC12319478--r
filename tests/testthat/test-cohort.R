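toy_table <- function() {
  data.frame(animal_id = rep(c("a1", "a2"), each = 2),
             group = "control",
             day = rep(c(0, 6), 2),
             metric = "tumor_volume",
             value = c(2, 3, 4, 4),
             survival_time = 6, event = 0)
}

test_that("percent change is computed per animal against baseline", {
  pc <- percent_change(toy_table())
  expect_equal(pc$value[pc$animal_id == "a1"], 50)
  expect_equal(pc$value[pc$animal_id == "a2"], 0)
})

test_that("zero or missing baselines are dropped with a warning", {
  tbl <- toy_table()
  tbl$value[tbl$animal_id == "a1" & tbl$day == 0] <- 0
  expect_warning(pc <- percent_change(tbl), "baseline")
  expect_false("a1" %in% pc$animal_id)

  tbl2 <- toy_table()[-1, ]  # a1 has no baseline row
  expect_warning(pc2 <- percent_change(tbl2), "baseline")
  expect_false("a1" %in% pc2$animal_id)
})

test_that("one-way ANOVA matches the textbook sum-of-squares computation", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grps <- rep(c("g1", "g2", "g3"), each = 3)
  res <- anova_bonferroni(vals, grps)
  # hand computation: group means 2,3,4; grand mean 3;
  # SSB = 3*(1+0+1) = 6 (df 2), SSW = 2+2+2 = 6 (df 6) -> F = 3/1 = 3
  expect_equal(res$F, 3, tolerance = 1e-10)
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  # agreement with the built-in fitter as a second, independent route
  expect_equal(res$F, summary(stats::aov(vals ~ factor(grps)))[[1]]$`F value`[1],
               tolerance = 1e-10)
})

test_that("identical constant groups give F = 0, p = 1", {
  res <- anova_bonferroni(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("Bonferroni adjustment multiplies, caps at 1 and is monotone", {
  vals <- c(rnorm(5), rnorm(5, 3), rnorm(5, 6))
  grps <- rep(c("a", "b", "c"), each = 5)
  res <- anova_bonferroni(vals, grps)
  expect_equal(res$m, 3)
  expect_equal(res$pairwise$adj_p, pmin(1, res$pairwise$raw_p * 3))
  expect_true(all(res$pairwise$adj_p >= res$pairwise$raw_p))
  res10 <- anova_bonferroni(vals, grps, m = 10)
  expect_equal(res10$pairwise$adj_p, pmin(1, res10$pairwise$raw_p * 10))
  # forced arithmetic: raw 0.02 with m = 3 adjusts to 0.06
  expect_equal(min(1, 0.02 * 3), 0.06)
})

test_that("ANOVA F is invariant to shift and positive scaling", {
  set.seed(31)
  vals <- c(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  grps <- rep(c("a", "b", "c"), each = 6)
  f0 <- anova_bonferroni(vals, grps)$F
  expect_equal(anova_bonferroni(vals + 100, grps)$F, f0, tolerance = 1e-10)
  expect_equal(anova_bonferroni(vals * 7.3, grps)$F, f0, tolerance = 1e-10)
})

test_that("pairwise power grows with n for truly different means", {
  set.seed(52)
  mns <- c(1.25, 1.68)
  vals <- c(rnorm(1000, mns[1], 0.01 * mns[1]), rnorm(1000, mns[2], 0.01 * mns[2]))
  grps <- rep(c("a", "b"), each = 1000)
  res <- anova_bonferroni(vals, grps)
  expect_lt(res$pairwise$adj_p, 1e-10)
})

test_that("Kaplan-Meier estimate matches the hand product-limit values", {
  rec <- data.frame(time = c(1, 2, 3), event = 1)
  km <- km_estimate(rec)
  expect_equal(km$curve$surv[km$curve$time == 1], 2 / 3)
  expect_equal(km$curve$surv[km$curve$time == 2], 1 / 3)
  expect_equal(km$curve$surv[km$curve$time == 3], 0)
  expect_equal(km$surv_fn(0), 1)

  cens <- data.frame(time = c(2, 4, 6), event = 0)
  km2 <- km_estimate(cens)
  expect_true(all(km2$curve$surv == 1))

  mixed <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  km3 <- km_estimate(mixed)
  oracle <- km_oracle(mixed$time, mixed$event)
  expect_equal(km3$curve$surv[match(oracle$time, km3$curve$time)], oracle$surv)
  # non-increasing step function with S(0) = 1
  expect_true(all(diff(km3$curve$surv) <= 0))
})

test_that("log-rank statistic matches the per-event-time tabulation oracle", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = 1,
                    group = rep(c("A", "B"), each = 2))
  r <- logrank_test(rec, "A", "B")
  o <- logrank_oracle(rec$time, rec$event, rec$group)
  expect_equal(r$chisq, o$chisq, tolerance = 1e-10)

  # one group fully censored before the other's first event
  rec2 <- data.frame(time = c(0.5, 0.5, 2, 3), event = c(0, 0, 1, 1),
                     group = rep(c("A", "B"), each = 2))
  r2 <- logrank_test(rec2, "A", "B")
  o2 <- logrank_oracle(rec2$time, rec2$event, rec2$group)
  expect_equal(r2$chisq, o2$chisq, tolerance = 1e-10)
})

test_that("log-rank is symmetric in the groups and null on identical data", {
  rec <- data.frame(time = c(1, 2, 5, 1, 2, 5), event = c(1, 1, 0, 1, 1, 0),
                    group = rep(c("A", "B"), each = 3))
  r <- logrank_test(rec, "A", "B")
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-10)
  set.seed(3)
  rec2 <- data.frame(time = rexp(20), event = rbinom(20, 1, 0.8),
                     group = rep(c("A", "B"), 10))
  expect_equal(logrank_test(rec2, "A", "B")$chisq,
               logrank_test(rec2, "B", "A")$chisq, tolerance = 1e-12)
})

test_that("run_study with zero SDs reproduces the analytic percent changes", {
  params <- default_cohort_params()
  params$sd <- 0
  co <- generate_cohort(cohort_spec(params = params, seed = 4))
  st <- suppressWarnings(run_study(co))
  pc <- st$percent_change
  combo_d6 <- pc$value[pc$metric == "D" & pc$day == 6 & pc$group == "MN58b+TMZ"]
  expect_true(all(abs(combo_d6 - 100 * (1.68 - 1.41) / 1.41) < 1e-9))
  ctrl_l6 <- pc$value[pc$metric == "Lip+Lac/tCr" & pc$day == 6 & pc$group == "control"]
  expect_true(all(abs(ctrl_l6 - 100 * (7.13 - 2.51) / 2.51) < 1e-9))
})

test_that("run_study ranks the combination arm as programmed", {
  # larger arms than the in vivo design so the programmed effect direction
  # dominates sampling noise
  n <- c(control = 30L, MN58b = 30L, TMZ = 30L, `MN58b+TMZ` = 30L)
  co <- generate_cohort(cohort_spec(n_per_group = n, seed = 1))
  st <- suppressWarnings(run_study(co))
  pc <- st$percent_change
  d6 <- pc[pc$metric == "D" & pc$day == 6, ]
  md <- tapply(d6$value, d6$group, mean)
  expect_equal(names(which.max(md)), "MN58b+TMZ")
  l6 <- pc[pc$metric == "Lip+Lac/tCr" & pc$day == 6, ]
  ml <- tapply(l6$value, l6$group, mean)
  expect_equal(names(which.min(ml)), "MN58b+TMZ")
  # day-6-only metrics are analysed on raw values
  expect_true("mitotic_index" %in% st$comparisons$metric)
  expect_equal(unique(st$comparisons$unit[st$comparisons$metric == "mitotic_index"]),
               "raw")
})
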