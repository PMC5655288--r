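test_that("one-way ANOVA matches the frozen sum-of-squares oracle", {
  g <- list(a = c(6, 8, 4, 5, 3, 4),
            b = c(8, 12, 9, 11, 6, 8),
            c = c(13, 9, 11, 8, 7, 12))
  res <- one_way_anova(g)
  # frozen from an independent brute-force between/within decomposition
  expect_equal(res$ss_between, 84)
  expect_equal(res$ss_within, 68)
  expect_equal(res$f_statistic, 9.2647058824, tolerance = 1e-9)
  expect_equal(res$p_value, 0.0023987773, tolerance = 1e-7)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 15)

  # cross-check against the standard linear-model route
  d <- data.frame(y = unlist(g), grp = rep(names(g), each = 6))
  ref <- summary(stats::aov(y ~ grp, d))[[1]]
  expect_equal(res$f_statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)

  # data-frame interface agrees with list interface
  res_df <- one_way_anova(d, y, grp)
  expect_equal(res_df$f_statistic, res$f_statistic)
})

test_that("degenerate ANOVA inputs follow the stated conventions", {
  identical_groups <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- one_way_anova(identical_groups)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)

  separated <- one_way_anova(list(c(0, 0), c(10, 10)))
  expect_equal(separated$f_statistic, Inf)
  expect_equal(separated$p_value, 0)

  expect_error(one_way_anova(list(c(1, 2))), "two groups",
               class = "trastucost_input_error")
  expect_error(one_way_anova(list(c(1, 2), 3)), "two observations",
               class = "trastucost_input_error")
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2))
    f <- one_way_anova(list(a, b))$f_statistic
    t <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2, tolerance = 1e-10)
  }
})

test_that("ANOVA is invariant to within-group permutation and location shift", {
  set.seed(5)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  res <- one_way_anova(g)
  permuted <- lapply(g, sample)
  expect_equal(one_way_anova(permuted)$f_statistic, res$f_statistic)
  shifted <- lapply(g, function(x) x + 100)
  expect_equal(one_way_anova(shifted)$f_statistic, res$f_statistic,
               tolerance = 1e-9)
})

test_that("Bonferroni adjustment caps at one and matches the standard route", {
  g <- list(a = c(1, 2, 3, 4), b = c(1.1, 2.2, 2.9, 4.1),
            c = c(10, 11, 12, 13))
  pw <- bonferroni_pairwise(g)
  expect_true(all(pw$p_adjusted >= pw$p_value))
  expect_true(all(pw$p_adjusted <= 1))
  expect_equal(pw$p_adjusted, pmin(1, 3 * pw$p_value))

  # per-pair pooled-variance t-tests via the standard route
  ref <- stats::pairwise.t.test(unlist(g), rep(names(g), each = 4),
                                p.adjust.method = "bonferroni",
                                pool.sd = FALSE, var.equal = TRUE)
  expect_equal(sort(pw$p_adjusted),
               sort(as.vector(stats::na.omit(as.vector(ref$p.value)))),
               tolerance = 1e-10)

  identical_groups <- list(c(1, 2), c(1, 2), c(1, 2))
  pw0 <- bonferroni_pairwise(identical_groups)
  expect_true(all(pw0$p_adjusted == 1))
})

test_that("post-hoc tests are gated on the omnibus result", {
  set.seed(2)
  flat <- list(rnorm(10), rnorm(10), rnorm(10))
  omnibus <- one_way_anova(flat)
  pw <- bonferroni_pairwise(flat, omnibus = omnibus)
  if (omnibus$p_value >= 0.05) {
    expect_false(any(pw$gate_passed))
    expect_false(any(pw$significant))
  }
  well_separated <- list(rnorm(10), rnorm(10, 50), rnorm(10, 100))
  omnibus2 <- one_way_anova(well_separated)
  pw2 <- bonferroni_pairwise(well_separated, omnibus = omnibus2)
  expect_true(all(pw2$gate_passed))
})

test_that("scenario workloads differ sharply across scenarios", {
  cohort <- example_cohort()
  results <- lapply(1:3, function(s) evaluate_scenario(cohort, s))
  cmp <- compare_scenarios(results, metric = "prep_hours")
  expect_lt(cmp$omnibus$p_value, 0.001)
  expect_true(all(cmp$pairwise$p_adjusted < 0.001))
  cmp_adm <- compare_scenarios(results, metric = "admin_hours")
  expect_lt(cmp_adm$omnibus$p_value, 0.001)

  # the repeated-measures alternative is available and at least as sharp
  cmp_rm <- compare_scenarios(results, metric = "prep_hours",
                              method = "repeated")
  expect_lt(cmp_rm$omnibus$p_value, 0.001)
  expect_equal(cmp_rm$omnibus$df_within, 113 * 2)
})
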