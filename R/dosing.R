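#' Dose schedule for intravenous and subcutaneous trastuzumab
#'
#' Weight-based intravenous dosing uses a loading dose followed by
#' maintenance doses: 4/2 mg/kg on the weekly cadence (given with
#' chemotherapy) and the label-standard 8/6 mg/kg on the every-three-weeks
#' cadence. The subcutaneous formulation is a fixed 600 mg dose at every
#' administration, with no pharmacological loading dose.
#'
#' @param weekly_loading_mg_per_kg,weekly_maintenance_mg_per_kg Weekly
#'   cadence coefficients, mg per kg body weight.
#' @param q3w_loading_mg_per_kg,q3w_maintenance_mg_per_kg Every-three-weeks
#'   cadence coefficients, mg per kg.
#' @param sc_fixed_mg Fixed subcutaneous dose in mg.
#' @return A `dose_schedule` list.
#' @export
dose_schedule <- function(weekly_loading_mg_per_kg = 4,
                          weekly_maintenance_mg_per_kg = 2,
                          q3w_loading_mg_per_kg = 8,
                          q3w_maintenance_mg_per_kg = 6,
                          sc_fixed_mg = 600) {
  s <- list(weekly_loading_mg_per_kg = weekly_loading_mg_per_kg,
            weekly_maintenance_mg_per_kg = weekly_maintenance_mg_per_kg,
            q3w_loading_mg_per_kg = q3w_loading_mg_per_kg,
            q3w_maintenance_mg_per_kg = q3w_maintenance_mg_per_kg,
            sc_fixed_mg = sc_fixed_mg)
  if (any(unlist(s) <= 0)) {
    rlang::abort("all dose coefficients must be strictly positive",
                 class = "trastucost_param_error")
  }
  if (weekly_loading_mg_per_kg < weekly_maintenance_mg_per_kg ||
      q3w_loading_mg_per_kg < q3w_maintenance_mg_per_kg) {
    rlang::abort("loading dose must be >= maintenance dose within a cadence",
                 class = "trastucost_param_error")
  }
  structure(s, class = "dose_schedule")
}

#' Weight-based intravenous dose
#'
#' Exact arithmetic (robotic preparation draws exact amounts; no vial
#' rounding): body weight times the mg/kg coefficient for the cadence and
#' role. Vectorized over its first three arguments.
#'
#' @param weight_kg Body weight(s) in kg, strictly positive.
#' @param cadence `"weekly"` or `"q3w"`.
#' @param role `"loading"` or `"maintenance"`.
#' @param schedule A [dose_schedule()].
#' @return Dose(s) in mg.
#' @export
#' @examples
#' iv_dose_mg(63.75, "weekly", "maintenance")  # 127.5
iv_dose_mg <- function(weight_kg, cadence, role, schedule = dose_schedule()) {
  if (any(!cadence %in% c("weekly", "q3w")) ||
      any(!role %in% c("loading", "maintenance"))) {
    rlang::abort("cadence must be weekly/q3w and role loading/maintenance",
                 class = "trastucost_domain_error")
  }
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    rlang::abort("weight_kg must be strictly positive",
                 class = "trastucost_domain_error")
  }
  coef <- mg_per_kg(cadence, role, schedule)
  weight_kg * coef
}

# mg/kg coefficient lookup, vectorized
mg_per_kg <- function(cadence, role, schedule = dose_schedule()) {
  key <- paste0(ifelse(cadence == "weekly", "weekly_", "q3w_"),
                ifelse(role == "loading", "loading", "maintenance"),
                "_mg_per_kg")
  unlist(schedule[key], use.names = FALSE)
}

#' Convert a weekly intravenous block to subcutaneous cycles
#'
#' Three weekly intravenous preparations are replaced by one subcutaneous
#' administration every three weeks; a partial block of one or two weekly
#' cycles still requires one subcutaneous administration (ceiling division).
#'
#' @param n_weekly_cycles Non-negative integer count(s) of weekly cycles.
#' @return Number of subcutaneous cycles, `ceiling(n / 3)`.
#' @export
#' @examples
#' convert_weekly_block_to_sc(3)  # 1
convert_weekly_block_to_sc <- function(n_weekly_cycles) {
  if (any(is.na(n_weekly_cycles)) || any(n_weekly_cycles < 0) ||
      any(n_weekly_cycles != round(n_weekly_cycles))) {
    rlang::abort("n_weekly_cycles must be non-negative integers",
                 class = "trastucost_domain_error")
  }
  as.integer(ceiling(n_weekly_cycles / 3))
}

# per-cycle chair/administration minutes: iv loading 90, iv maintenance 30,
# sc 5 (any role)
admin_minutes_for <- function(formulation, role, costs = unit_costs()) {
  am <- costs$admin_minutes
  ifelse(formulation == "SC", am[["sc"]],
         ifelse(role == "loading", am[["iv_loading"]], am[["iv_maintenance"]]))
}

#' Expand a cohort into per-cycle plans for a treatment scenario
#'
#' Scenario 1 keeps every cycle intravenous at its recorded cadence and role.
#' Scenario 2 replaces each weekly phase by `ceiling(n/3)` subcutaneous
#' cycles and each q3w cycle by one subcutaneous cycle. Scenario 3 keeps
#' weekly (chemo-concurrent) phases intravenous and switches q3w phases to
#' subcutaneous 1:1. Subcutaneous cycles are always the fixed dose with a
#' 5-minute administration; the first converted cycle of a weekly block that
#' contained a loading keeps the `loading` label for bookkeeping, with no
#' effect on dose or time.
#'
#' @param cohort A cohort tibble.
#' @param scenario Scenario id: 1, 2 or 3.
#' @param schedule A [dose_schedule()].
#' @param costs A [unit_costs()]; supplies the per-cycle administration
#'   minutes.
#' @return A tibble with one row per administration event: `patient_id`,
#'   `scenario`, `formulation` (`"IV"`/`"SC"`), `cadence`, `role`,
#'   `dose_mg`, `admin_minutes`.
#' @export
#' @examples
#' plans <- plan_scenario(example_cohort(), scenario = 3)
#' dplyr::count(plans, formulation)
plan_scenario <- function(cohort, scenario, schedule = dose_schedule(),
                          costs = unit_costs()) {
  cohort <- validate_cohort(cohort)
  if (!scenario %in% 1:3) {
    rlang::abort("scenario must be 1, 2 or 3",
                 class = "trastucost_domain_error")
  }
  phase_cycles <- function(ph) {
    n <- ph$n_loading + ph$n_maintenance
    tibble::tibble(
      patient_id = ph$id,
      cadence = ph$cadence,
      role = rep(c("loading", "maintenance"),
                 c(ph$n_loading, ph$n_maintenance)),
      weight_kg = ph$weight_kg
    )[seq_len(n), ]
  }
  plan_phase <- function(ph) {
    iv_phase <- (scenario == 1) ||
      (scenario == 3 && ph$cadence == "weekly")
    if (iv_phase) {
      cyc <- phase_cycles(ph)
      cyc$formulation <- "IV"
      cyc$dose_mg <- iv_dose_mg(cyc$weight_kg, cyc$cadence, cyc$role, schedule)
    } else if (ph$cadence == "q3w") {
      cyc <- phase_cycles(ph)          # 1:1 switch, roles kept
      cyc$formulation <- "SC"
      cyc$dose_mg <- schedule$sc_fixed_mg
    } else {
      n_sc <- convert_weekly_block_to_sc(ph$n_loading + ph$n_maintenance)
      cyc <- tibble::tibble(
        patient_id = ph$id,
        cadence = "q3w",
        role = rep(c("loading", "maintenance"),
                   c(min(ph$n_loading, n_sc), max(n_sc - ph$n_loading, 0))),
        weight_kg = ph$weight_kg,
        formulation = "SC",
        dose_mg = schedule$sc_fixed_mg
      )
    }
    cyc
  }
  plans <- cohort |>
    dplyr::rowwise() |>
    dplyr::group_split() |>
    purrr::map(plan_phase) |>
    dplyr::bind_rows()
  plans$scenario <- as.integer(scenario)
  plans$admin_minutes <- admin_minutes_for(plans$formulation, plans$role, costs)
  dplyr::select(plans, "patient_id", "scenario", "formulation", "cadence",
                "role", "dose_mg", "admin_minutes")
}

#' Tally drug mass and cycles by formulation
#'
#' @param plans A cycle-plan tibble from [plan_scenario()], or several
#'   scenarios' plans row-bound (tallied jointly).
#' @return One-row tibble: `iv_mg`, `sc_mg`, `iv_cycles`, `sc_cycles`,
#'   `delta_mg` (sc - iv) and `delta_pct` (100 * delta / iv; `NA` when no
#'   intravenous mass is present).
#' @export
tally_drug <- function(plans) {
  iv <- plans$formulation == "IV"
  iv_mg <- sum(plans$dose_mg[iv])
  sc_mg <- sum(plans$dose_mg[!iv])
  tibble::tibble(
    iv_mg = iv_mg, sc_mg = sc_mg,
    iv_cycles = sum(iv), sc_cycles = sum(!iv),
    delta_mg = sc_mg - iv_mg,
    delta_pct = if (iv_mg > 0) 100 * (sc_mg - iv_mg) / iv_mg else NA_real_
  )
}
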