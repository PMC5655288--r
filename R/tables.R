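#' Report tables for a set of scenario results
#'
#' Builds the three summary tables of the cost-minimization analysis:
#' drug mass by weight quartile, workload times with percentage reductions
#' relative to scenario 1, and mean cost per patient by component. All
#' values are unrounded; formatting to printed precision is left to
#' [format_report_tables()].
#'
#' @param results List of `scenario_result` objects (any subset of
#'   scenarios; reductions are reported against scenario 1 when present).
#' @param cohort The cohort the results were computed from (needed for the
#'   weight-quartile table).
#' @param schedule,costs The [dose_schedule()] and [unit_costs()] used.
#' @return List of tibbles: `drug_mass` (per-quartile intravenous and
#'   subcutaneous mg), `workload` (preparation/administration metrics by
#'   scenario with `pct_reduction_vs_1`), `cost_per_patient` (component
#'   means and sds by scenario).
#' @export
scenario_tables <- function(results, cohort, schedule = dose_schedule(),
                            costs = unit_costs()) {
  stopifnot(length(results) >= 1)
  names(results) <- vapply(results, function(r) as.character(r$scenario), "")

  drug_mass <- quartile_drug_table(cohort, schedule, costs)

  workload <- purrr::map_dfr(results, function(r) {
    tibble::tibble(
      scenario = r$scenario,
      n_cycles = r$drug_totals$iv_cycles + r$drug_totals$sc_cycles,
      prep_hours = r$time_profile$overall_prep_hours,
      admin_hours = r$time_profile$overall_admin_hours,
      mean_prep_hours = r$time_profile$mean_prep_hours_per_patient,
      mean_admin_hours = r$time_profile$mean_admin_hours_per_patient
    )
  })
  if ("1" %in% names(results)) {
    ref <- workload[match(1, workload$scenario), ]
    workload <- workload |>
      dplyr::mutate(
        prep_pct_reduction_vs_1 = 100 * (ref$prep_hours - .data$prep_hours) /
          ref$prep_hours,
        admin_pct_reduction_vs_1 = 100 * (ref$admin_hours - .data$admin_hours) /
          ref$admin_hours
      )
  }

  cost_per_patient <- purrr::map_dfr(results, function(r) {
    pp <- r$per_patient
    tibble::tibble(
      scenario = r$scenario,
      direct_mean = mean(pp$drug_eur + pp$waste_eur),
      direct_sd = stats::sd(pp$drug_eur + pp$waste_eur),
      prep_mean = mean(pp$prep_eur),
      prep_sd = stats::sd(pp$prep_eur),
      clinic_mean = mean(pp$clinic_eur),
      clinic_sd = stats::sd(pp$clinic_eur),
      global_mean = mean(pp$global_eur),
      global_sd = stats::sd(pp$global_eur)
    )
  })

  list(drug_mass = drug_mass, workload = workload,
       cost_per_patient = cost_per_patient)
}

# per-weight-quartile drug mass: intravenous mg under scenario 1 vs
# subcutaneous mg under scenario 2, patients binned at the quartile bounds
quartile_drug_table <- function(cohort, schedule = dose_schedule(),
                                costs = unit_costs()) {
  cohort <- validate_cohort(cohort)
  p1 <- plan_scenario(cohort, 1, schedule, costs) |>
    dplyr::summarise(iv_mg = sum(.data$dose_mg), .by = "patient_id")
  p2 <- plan_scenario(cohort, 2, schedule, costs) |>
    dplyr::summarise(sc_mg = sum(.data$dose_mg), .by = "patient_id")
  patients <- dplyr::distinct(cohort, patient_id = .data$id, .data$weight_kg)
  q <- stats::quantile(patients$weight_kg, c(0.25, 0.5, 0.75),
                       names = FALSE, type = 7)
  brk <- c(-Inf, q, Inf)
  patients |>
    dplyr::left_join(p1, by = "patient_id") |>
    dplyr::left_join(p2, by = "patient_id") |>
    dplyr::mutate(quartile = paste0("Q", findInterval(
      .data$weight_kg, brk[2:4], left.open = TRUE) + 1)) |>
    dplyr::summarise(upper_bound_kg = max(.data$weight_kg),
                     iv_mg = sum(.data$iv_mg), sc_mg = sum(.data$sc_mg),
                     delta_mg = sum(.data$sc_mg) - sum(.data$iv_mg),
                     .by = "quartile") |>
    dplyr::arrange(.data$quartile)
}

#' Format report tables at printed precision
#'
#' Rounds the unrounded [scenario_tables()] output the way such results are
#' conventionally printed: workload hours to the nearest hour, percentages
#' to one decimal, euro means to one decimal with thousands separators kept
#' out of machine output.
#'
#' @param tables A [scenario_tables()] list.
#' @return A list of tibbles with rounded display columns.
#' @export
format_report_tables <- function(tables) {
  list(
    drug_mass = dplyr::mutate(tables$drug_mass,
                              dplyr::across(dplyr::ends_with("_mg"), round)),
    workload = dplyr::mutate(
      tables$workload,
      dplyr::across(dplyr::ends_with("_hours"), round),
      dplyr::across(dplyr::contains("pct"), ~ round(.x, 1))
    ),
    cost_per_patient = dplyr::mutate(
      tables$cost_per_patient,
      dplyr::across(dplyr::where(is.double), ~ round(.x, 1))
    )
  )
}

# euro amount with thousands separator, for human-readable printing
format_eur <- function(x, digits = 0) {
  formatC(round(x, digits), format = "f", digits = digits, big.mark = ",")
}
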