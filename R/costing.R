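#' Unit costs, rates, times and the waste fraction
#'
#' Defaults are the published 2014 Italian institutional constants: drug
#' prices per mg by formulation, per-cycle robotic preparation costs, the
#' outpatient-clinic occupancy rate, staff rates (kept for sensitivity use;
#' the per-cycle preparation costs are used as printed, not re-derived from
#' staff rates), the preparation-stage waste fraction applied to intravenous
#' drug spend, and per-cycle administration (chair) minutes.
#'
#' Two preparation times are carried per formulation. `unit_prep_seconds_*`
#' are the robot's measured per-preparation times (844 s intravenous, 641 s
#' subcutaneous), used for the per-cycle preparation-time reduction
#' statistic. `effective_prep_seconds_*` are the per-cycle times that
#' reproduce the published overall preparation workloads (120 h over 1,292
#' intravenous cycles; 34 h over 937 subcutaneous cycles) and are the ones
#' used in cost aggregation; the two sets are mutually inconsistent in the
#' source aggregates and are deliberately kept separate.
#'
#' @param iv_eur_per_mg,sc_eur_per_mg Drug price, euro per mg.
#' @param prep_cost_iv_per_cycle_eur,prep_cost_sc_per_cycle_eur Preparation
#'   labour cost per cycle, euro.
#' @param clinic_eur_per_hour Outpatient-clinic occupancy rate, euro/hour.
#' @param technician_eur_per_hour,pharmacist_eur_per_hour Staff rates,
#'   euro/hour (sensitivity analyses only).
#' @param waste_fraction Fraction of intravenous drug spend lost to
#'   preparation waste, in \[0, 1).
#' @param unit_prep_seconds_iv,unit_prep_seconds_sc Measured per-preparation
#'   seconds.
#' @param effective_prep_seconds_iv,effective_prep_seconds_sc Per-cycle
#'   seconds used in workload aggregation.
#' @param admin_minutes Named numeric: chair minutes for `iv_loading`,
#'   `iv_maintenance` and `sc` cycles.
#' @return A `unit_costs` list.
#' @export
unit_costs <- function(iv_eur_per_mg = 4.15,
                       sc_eur_per_mg = 2.87,
                       prep_cost_iv_per_cycle_eur = 8.17,
                       prep_cost_sc_per_cycle_eur = 6.99,
                       clinic_eur_per_hour = 89.80,
                       technician_eur_per_hour = 21,
                       pharmacist_eur_per_hour = 60,
                       waste_fraction = 0.0011,
                       unit_prep_seconds_iv = 844,
                       unit_prep_seconds_sc = 641,
                       effective_prep_seconds_iv = 120 * 3600 / 1292,
                       effective_prep_seconds_sc = 34 * 3600 / 937,
                       admin_minutes = c(iv_loading = 90,
                                         iv_maintenance = 30,
                                         sc = 5)) {
  u <- list(iv_eur_per_mg = iv_eur_per_mg, sc_eur_per_mg = sc_eur_per_mg,
            prep_cost_iv_per_cycle_eur = prep_cost_iv_per_cycle_eur,
            prep_cost_sc_per_cycle_eur = prep_cost_sc_per_cycle_eur,
            clinic_eur_per_hour = clinic_eur_per_hour,
            technician_eur_per_hour = technician_eur_per_hour,
            pharmacist_eur_per_hour = pharmacist_eur_per_hour,
            waste_fraction = waste_fraction,
            unit_prep_seconds_iv = unit_prep_seconds_iv,
            unit_prep_seconds_sc = unit_prep_seconds_sc,
            effective_prep_seconds_iv = effective_prep_seconds_iv,
            effective_prep_seconds_sc = effective_prep_seconds_sc,
            admin_minutes = admin_minutes)
  if (any(unlist(u) < 0)) {
    rlang::abort("all unit costs, times and rates must be non-negative",
                 class = "trastucost_param_error")
  }
  if (waste_fraction >= 1) {
    rlang::abort("waste_fraction must lie in [0, 1)",
                 class = "trastucost_param_error")
  }
  if (!all(c("iv_loading", "iv_maintenance", "sc") %in% names(admin_minutes))) {
    rlang::abort("admin_minutes must name iv_loading, iv_maintenance and sc",
                 class = "trastucost_param_error")
  }
  structure(u, class = "unit_costs")
}

#' Drug acquisition cost
#'
#' @param totals A [tally_drug()] row.
#' @param costs A [unit_costs()].
#' @return One-row tibble `iv_eur`, `sc_eur`, `total_eur`.
#' @export
#' @examples
#' drug_cost(tibble::tibble(iv_mg = 372214, sc_mg = 0))
drug_cost <- function(totals, costs = unit_costs()) {
  iv <- totals$iv_mg * costs$iv_eur_per_mg
  sc <- totals$sc_mg * costs$sc_eur_per_mg
  tibble::tibble(iv_eur = iv, sc_eur = sc, total_eur = iv + sc)
}

#' Preparation-stage drug waste cost
#'
#' Waste applies to the intravenous drug spend only; the subcutaneous
#' formulation is a fixed prefilled dose and incurs none.
#'
#' @param iv_drug_cost_eur Intravenous drug spend in euro.
#' @param costs A [unit_costs()].
#' @return Waste cost in euro.
#' @export
waste_cost <- function(iv_drug_cost_eur, costs = unit_costs()) {
  stopifnot(iv_drug_cost_eur >= 0)
  costs$waste_fraction * iv_drug_cost_eur
}

#' Preparation workload and cost profile
#'
#' Hours use the effective per-cycle preparation seconds; cost uses the
#' per-cycle preparation prices.
#'
#' @param plans A cycle-plan tibble.
#' @param costs A [unit_costs()].
#' @return List with `hours_total`, `eur_total` and a `per_patient` tibble
#'   (`patient_id`, `hours`, `eur`).
#' @export
prep_profile <- function(plans, costs = unit_costs()) {
  secs <- ifelse(plans$formulation == "IV",
                 costs$effective_prep_seconds_iv,
                 costs$effective_prep_seconds_sc)
  eur <- ifelse(plans$formulation == "IV",
                costs$prep_cost_iv_per_cycle_eur,
                costs$prep_cost_sc_per_cycle_eur)
  per_patient <- tibble::tibble(patient_id = plans$patient_id,
                                hours = secs / 3600, eur = eur) |>
    dplyr::summarise(hours = sum(.data$hours), eur = sum(.data$eur),
                     .by = "patient_id")
  list(hours_total = sum(secs) / 3600, eur_total = sum(eur),
       per_patient = per_patient)
}

#' Administration (chair-time) profile
#'
#' @param plans A cycle-plan tibble carrying `admin_minutes`.
#' @return List with `hours_total` and a `per_patient` tibble.
#' @export
admin_profile <- function(plans) {
  per_patient <- plans |>
    dplyr::summarise(hours = sum(.data$admin_minutes) / 60,
                     .by = "patient_id") |>
    dplyr::rename(patient_id = "patient_id")
  list(hours_total = sum(plans$admin_minutes) / 60, per_patient = per_patient)
}

#' Outpatient-clinic occupancy cost
#'
#' @param admin_hours Chair hours (unrounded).
#' @param costs A [unit_costs()].
#' @return Cost in euro.
#' @export
clinic_cost <- function(admin_hours, costs = unit_costs()) {
  stopifnot(admin_hours >= 0)
  admin_hours * costs$clinic_eur_per_hour
}

#' Evaluate one treatment scenario over a cohort
#'
#' Expands the cohort into cycle plans, then composes drug, waste,
#' preparation and clinic costing into scenario totals and per-patient cost
#' vectors. Waste is attributed to patients in proportion to their
#' intravenous drug spend, so per-patient breakdowns sum exactly to the
#' totals.
#'
#' @param cohort A cohort tibble.
#' @param scenario Scenario id: 1 (all intravenous), 2 (all subcutaneous),
#'   3 (intravenous during chemotherapy, then subcutaneous).
#' @param schedule A [dose_schedule()].
#' @param costs A [unit_costs()].
#' @return A `scenario_result` object: `scenario`, `n_patients`, `totals`
#'   (one-row tibble: `drug_eur`, `waste_eur`, `prep_eur`, `clinic_eur`,
#'   `global_eur`), `per_patient` (tibble of the same components plus
#'   `prep_hours`, `admin_hours` per patient), `time_profile` and
#'   `drug_totals`. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
#' @examples
#' res <- evaluate_scenario(example_cohort(), scenario = 2)
#' glance(res)
evaluate_scenario <- function(cohort, scenario, schedule = dose_schedule(),
                              costs = unit_costs()) {
  cohort <- validate_cohort(cohort)
  plans <- plan_scenario(cohort, scenario, schedule, costs)
  patients <- dplyr::distinct(cohort, patient_id = .data$id)
  tal <- tally_drug(plans)
  dc <- drug_cost(tal, costs)
  prep <- prep_profile(plans, costs)
  adm <- admin_profile(plans)

  per_drug <- plans |>
    dplyr::mutate(eur = .data$dose_mg *
                    ifelse(.data$formulation == "IV",
                           costs$iv_eur_per_mg, costs$sc_eur_per_mg),
                  iv_eur = .data$eur * (.data$formulation == "IV")) |>
    dplyr::summarise(drug_eur = sum(.data$eur),
                     waste_eur = costs$waste_fraction * sum(.data$iv_eur),
                     .by = "patient_id")

  per_patient <- patients |>
    dplyr::left_join(per_drug, by = "patient_id") |>
    dplyr::left_join(dplyr::rename(prep$per_patient, prep_hours = "hours",
                                   prep_eur = "eur"),
                     by = "patient_id") |>
    dplyr::left_join(dplyr::rename(adm$per_patient, admin_hours = "hours"),
                     by = "patient_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0)),
                  clinic_eur = .data$admin_hours * costs$clinic_eur_per_hour,
                  global_eur = .data$drug_eur + .data$waste_eur +
                    .data$prep_eur + .data$clinic_eur)

  clinic <- clinic_cost(adm$hours_total, costs)
  totals <- tibble::tibble(
    drug_eur = dc$total_eur,
    waste_eur = waste_cost(dc$iv_eur, costs),
    prep_eur = prep$eur_total,
    clinic_eur = clinic,
    global_eur = dc$total_eur + waste_cost(dc$iv_eur, costs) +
      prep$eur_total + clinic
  )
  n <- nrow(patients)
  structure(list(
    scenario = as.integer(scenario),
    n_patients = n,
    totals = totals,
    per_patient = per_patient,
    time_profile = list(
      overall_prep_hours = prep$hours_total,
      overall_admin_hours = adm$hours_total,
      mean_prep_hours_per_patient = prep$hours_total / n,
      mean_admin_hours_per_patient = adm$hours_total / n
    ),
    drug_totals = tal
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario", x$scenario, "over", x$n_patients, "patients\n")
  cat(sprintf("  drug %s + waste %s + prep %s + clinic %s = global %s EUR\n",
              format(round(x$totals$drug_eur), big.mark = ","),
              format(round(x$totals$waste_eur), big.mark = ","),
              format(round(x$totals$prep_eur), big.mark = ","),
              format(round(x$totals$clinic_eur), big.mark = ","),
              format(round(x$totals$global_eur), big.mark = ",")))
  cat(sprintf("  prep %.1f h, chair %.1f h; mean global %.1f EUR/patient\n",
              x$time_profile$overall_prep_hours,
              x$time_profile$overall_admin_hours,
              x$totals$global_eur / x$n_patients))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-patient cost breakdown of a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return The per-patient tibble with a `scenario` column prepended.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  dplyr::mutate(x$per_patient, scenario = x$scenario, .before = 1)
}

#' One-row summary of a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return One-row tibble: scenario, patient count, cost totals, overall and
#'   mean workload hours, and mean/sd global cost per patient.
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    n_patients = x$n_patients,
    drug_eur = x$totals$drug_eur,
    waste_eur = x$totals$waste_eur,
    prep_eur = x$totals$prep_eur,
    clinic_eur = x$totals$clinic_eur,
    global_eur = x$totals$global_eur,
    prep_hours = x$time_profile$overall_prep_hours,
    admin_hours = x$time_profile$overall_admin_hours,
    mean_global_eur = x$totals$global_eur / x$n_patients,
    sd_global_eur = stats::sd(x$per_patient$global_eur)
  )
}
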