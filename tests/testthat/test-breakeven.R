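test_that("per-kg calibration matches direct arithmetic", {
  cal <- calibrate_per_kg(reference_counts(), total_iv_mg = 372214)
  expect_equal(cal$per_kg_dose_total, 53 * 4 + 490 * 2 + 32 * 8 + 717 * 6)
  expect_equal(cal$per_kg_dose_total, 5750)
  expect_equal(round(cal$implied_mean_weight_kg, 1), 64.7)

  single <- calibrate_per_kg(c(q3w_maintenance = 1), total_iv_mg = 360)
  expect_equal(single$implied_mean_weight_kg, 60)

  expect_error(calibrate_per_kg(c(q3w_maintenance = 0), total_iv_mg = 100),
               class = "trastucost_calibration_error")
  expect_error(calibrate_per_kg(c(monthly_loading = 1), total_iv_mg = 100),
               class = "trastucost_domain_error")
})

test_that("cost curves have the stated slopes and intercepts", {
  c1 <- cost_curve(1, list(iv_counts = reference_counts(), sc_cycles = 0))
  expect_equal(c1$slope_eur_per_kg, 4.15 * 5750 * 1.0011)
  c2 <- cost_curve(2, list(iv_counts = numeric(0), sc_cycles = 937))
  expect_equal(c2$slope_eur_per_kg, 0)
  expect_equal(c2$intercept_eur, 1613514 + 937 * 6.99 + 937 * 5 / 60 * 89.80)
  expect_equal(round(c2$intercept_eur), 1627076)

  degenerate <- cost_curve(1, list(iv_counts = reference_counts(),
                                   sc_cycles = 0),
                           costs = unit_costs(iv_eur_per_mg = 0,
                                              waste_fraction = 0))
  expect_equal(degenerate$slope_eur_per_kg, 0)
})

test_that("break-even solves intersections, parallels and identical curves", {
  a <- structure(list(scenario = 1L, slope_eur_per_kg = 1, intercept_eur = 0,
                      validity_range_kg = c(40, 100)), class = "cost_curve")
  b <- structure(list(scenario = 2L, slope_eur_per_kg = 0, intercept_eur = 10,
                      validity_range_kg = c(40, 100)), class = "cost_curve")
  expect_equal(breakeven_weight(a, b), 10)
  expect_equal(breakeven_weight(b, a), 10)  # symmetric
  par <- structure(list(scenario = 2L, slope_eur_per_kg = 1,
                        intercept_eur = 5, validity_range_kg = c(40, 100)),
                   class = "cost_curve")
  expect_true(is.na(breakeven_weight(a, par)))
  expect_equal(breakeven_weight(a, a), c(40, 100))
})

test_that("calibrated model breaks even near 65 kg", {
  fit <- fit_breakeven(reference_counts(), total_iv_mg = 372214,
                       sc_cycles = 937)
  expect_lt(abs(fit$breakeven_kg - 65.2), 1)
  # price sensitivities move the break-even in opposite directions
  dearer_iv <- fit_breakeven(reference_counts(), 372214, 937,
                             costs = unit_costs(iv_eur_per_mg = 4.5))
  expect_lt(dearer_iv$breakeven_kg, fit$breakeven_kg)
  dearer_sc <- fit_breakeven(reference_counts(), 372214, 937,
                             costs = unit_costs(sc_eur_per_mg = 3.2))
  expect_gt(dearer_sc$breakeven_kg, fit$breakeven_kg)
})

test_that("scenario-1 curve reproduces the bottom-up total at the implied weight", {
  cohort <- example_cohort()
  fit <- fit_breakeven_cohort(cohort)
  r1 <- evaluate_scenario(cohort, 1)
  at_mean <- fit$curves[[1]]$slope_eur_per_kg *
    fit$calibration$implied_mean_weight_kg + fit$curves[[1]]$intercept_eur
  expect_lt(abs(at_mean - r1$totals$global_eur) / r1$totals$global_eur, 0.001)
})

test_that("curve tables order scenarios correctly around the break-even", {
  fit <- fit_breakeven(reference_counts(), 372214, 937)
  be <- fit$breakeven_kg
  tab <- curve_table(fit$curves, c(55, be, 75)) |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "total_eur",
                       names_prefix = "s")
  expect_lt(tab$s1[tab$weight_kg == 55], tab$s2[tab$weight_kg == 55])
  expect_equal(tab$s1[tab$weight_kg == be], tab$s2[tab$weight_kg == be])
  expect_gt(tab$s1[tab$weight_kg == 75], tab$s2[tab$weight_kg == 75])

  expect_equal(nrow(curve_table(fit$curves, numeric(0))), 0)
  s2col <- curve_table(fit$curves[2], c(50, 60, 70))
  expect_equal(length(unique(s2col$total_eur)), 1)
})

test_that("tidy, glance and autoplot work on the break-even model", {
  fit <- fit_breakeven(reference_counts(), 372214, 937)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(td$slope_eur_per_kg[td$scenario == 2], 0)
  gl <- glance(fit)
  expect_equal(gl$per_kg_dose_total, 5750)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
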