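test_that("component costs match the printed unit arithmetic", {
  expect_equal(round(drug_cost(tibble::tibble(iv_mg = 372214, sc_mg = 0))$iv_eur),
               1544688)
  expect_equal(round(drug_cost(tibble::tibble(iv_mg = 0, sc_mg = 562200))$sc_eur),
               1613514)
  expect_equal(drug_cost(tibble::tibble(iv_mg = 0, sc_mg = 0))$total_eur, 0)

  expect_equal(round(waste_cost(1544688)), 1699)
  expect_equal(waste_cost(0), 0)
  expect_equal(round(waste_cost(322497)), 355)

  expect_equal(round(clinic_cost(731)), 65644)
  expect_equal(round(clinic_cost(4685 / 60)), 7012)
  expect_equal(clinic_cost(0), 0)
})

test_that("preparation and administration profiles reproduce workload hours", {
  cohort <- example_cohort()
  p1 <- plan_scenario(cohort, 1)
  p2 <- plan_scenario(cohort, 2)
  p3 <- plan_scenario(cohort, 3)
  expect_equal(prep_profile(p1)$hours_total, 120)
  expect_equal(prep_profile(p2)$hours_total, 34)
  expect_equal(round(prep_profile(p3)$hours_total), 78)
  expect_equal(admin_profile(p1)$hours_total, 731)
  expect_equal(round(admin_profile(p2)$hours_total, 2), 78.08)
  expect_equal(round(admin_profile(p3)$hours_total), 387)
})

test_that("scenario evaluation reproduces printed per-patient means", {
  cohort <- example_cohort()
  r1 <- evaluate_scenario(cohort, 1)
  r2 <- evaluate_scenario(cohort, 2)
  expect_equal(round(r1$totals$global_eur / 114, 1), 14233.2)
  expect_equal(round(r2$totals$global_eur / 114, 1), 14272.6)
  expect_equal(round(r1$totals$clinic_eur / 114, 2), 575.82)
})

test_that("per-patient breakdowns are additive and sum to totals", {
  cohort <- example_cohort()
  for (s in 1:3) {
    r <- evaluate_scenario(cohort, s)
    pp <- r$per_patient
    expect_equal(pp$global_eur,
                 pp$drug_eur + pp$waste_eur + pp$prep_eur + pp$clinic_eur)
    expect_equal(sum(pp$global_eur), r$totals$global_eur,
                 tolerance = 1e-9)
    expect_equal(sum(pp$drug_eur), r$totals$drug_eur, tolerance = 1e-9)
    expect_equal(sum(pp$waste_eur), r$totals$waste_eur, tolerance = 1e-9)
  }
})

test_that("evaluation equals a brute-force per-cycle ledger on small cohorts", {
  cohort <- tiny_cohort()
  for (s in 1:3) {
    r <- evaluate_scenario(cohort, s)
    oracle <- ledger_oracle(plan_scenario(cohort, s))
    joined <- merge(r$per_patient, oracle, by = "patient_id")
    expect_equal(joined$drug_eur, joined$drug, tolerance = 1e-12)
    expect_equal(joined$waste_eur, joined$waste, tolerance = 1e-12)
    expect_equal(joined$prep_eur, joined$prep, tolerance = 1e-12)
    expect_equal(joined$clinic_eur, joined$clinic, tolerance = 1e-12)
    expect_equal(joined$global_eur, joined$global, tolerance = 1e-12)
  }
})

test_that("costs are order-invariant and homogeneous in unit prices", {
  cohort <- tiny_cohort()
  r <- evaluate_scenario(cohort, 1)
  shuffled <- cohort[c(3, 1, 2), ]
  r_sh <- evaluate_scenario(shuffled, 1)
  expect_equal(r$totals, r_sh$totals)

  k <- 3.7
  scaled <- unit_costs(
    iv_eur_per_mg = 4.15 * k, sc_eur_per_mg = 2.87 * k,
    prep_cost_iv_per_cycle_eur = 8.17 * k,
    prep_cost_sc_per_cycle_eur = 6.99 * k,
    clinic_eur_per_hour = 89.80 * k,
    technician_eur_per_hour = 21 * k, pharmacist_eur_per_hour = 60 * k
  )
  r_k <- evaluate_scenario(cohort, 1, costs = scaled)
  expect_equal(r_k$totals$global_eur, k * r$totals$global_eur,
               tolerance = 1e-12)
  expect_equal(r_k$time_profile, r$time_profile)
})

test_that("scenario 2 totals are invariant to weight permutation", {
  cohort <- example_cohort()
  patients <- unique(cohort$id)
  set.seed(1)
  perm <- stats::setNames(sample(unique(cohort$weight_kg)), patients)
  permuted <- cohort
  permuted$weight_kg <- perm[permuted$id]
  expect_equal(evaluate_scenario(permuted, 2)$totals,
               evaluate_scenario(cohort, 2)$totals)
})

test_that("a single patient with zero relevant costs yields zeros", {
  cohort <- one_patient_cohort()
  free <- unit_costs(iv_eur_per_mg = 0, sc_eur_per_mg = 0,
                     prep_cost_iv_per_cycle_eur = 0,
                     prep_cost_sc_per_cycle_eur = 0,
                     clinic_eur_per_hour = 0, waste_fraction = 0)
  r <- evaluate_scenario(cohort, 1, costs = free)
  expect_equal(r$totals$global_eur, 0)
  expect_equal(r$per_patient$global_eur, 0)
})

test_that("report tables carry the printed workload reductions", {
  cohort <- example_cohort()
  results <- lapply(1:3, function(s) evaluate_scenario(cohort, s))
  tabs <- scenario_tables(results, cohort)
  wl <- tabs$workload
  expect_equal(round(wl$prep_pct_reduction_vs_1[wl$scenario == 2], 1), 71.7)
  expect_equal(round(wl$admin_pct_reduction_vs_1[wl$scenario == 2], 1), 89.3)
  expect_equal(wl$prep_pct_reduction_vs_1[wl$scenario == 1], 0)
  expect_equal(round(wl$admin_pct_reduction_vs_1[wl$scenario == 3]), 47)

  cpp <- tabs$cost_per_patient
  expect_equal(round(cpp$global_mean[cpp$scenario == 1], 1), 14233.2)
  expect_equal(round(cpp$global_mean[cpp$scenario == 2], 1), 14272.6)

  dm <- tabs$drug_mass
  expect_equal(sum(dm$iv_mg), 372214, tolerance = 1e-6)
  expect_equal(sum(dm$sc_mg), 562200)
  expect_equal(nrow(dm), 4)

  identical_tabs <- scenario_tables(list(results[[1]], results[[1]]), cohort)
  wl2 <- identical_tabs$workload
  expect_true(all(wl2$prep_pct_reduction_vs_1 == 0))
})

test_that("tidy and glance expose per-patient and summary views", {
  r <- evaluate_scenario(example_cohort(), 2)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 114)
  gl <- glance(r)
  expect_equal(gl$scenario, 2)
  expect_equal(round(gl$mean_global_eur, 1), 14272.6)
})
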