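#' Calibrate the cohort-level per-kg dose total
#'
#' For a frozen intravenous cycle structure, the cohort's total drug mass is
#' `sum_i weight_i * c_i`, where `c_i` is patient i's summed mg/kg
#' coefficient. At cohort level this collapses to
#' `per_kg_dose_total * implied_mean_weight`, where `per_kg_dose_total` is
#' the count-weighted sum of the mg/kg coefficients. Given a printed total
#' drug mass, the implied (dose-weighted) mean body weight follows by
#' division; it is derived, never assumed.
#'
#' @param cycle_counts Named counts: `weekly_loading`, `weekly_maintenance`,
#'   `q3w_loading`, `q3w_maintenance`.
#' @param schedule A [dose_schedule()].
#' @param total_iv_mg Total intravenous drug mass in mg.
#' @return List with `per_kg_dose_total` (mg per kg) and
#'   `implied_mean_weight_kg`.
#' @export
#' @examples
#' calibrate_per_kg(
#'   c(weekly_loading = 53, weekly_maintenance = 490,
#'     q3w_loading = 32, q3w_maintenance = 717),
#'   total_iv_mg = 372214
#' )
calibrate_per_kg <- function(cycle_counts, schedule = dose_schedule(),
                             total_iv_mg) {
  per_kg <- per_kg_dose_total(cycle_counts, schedule)
  if (per_kg <= 0) {
    rlang::abort("cycle structure has zero per-kg dose total",
                 class = "trastucost_calibration_error")
  }
  stopifnot(total_iv_mg > 0)
  list(per_kg_dose_total = per_kg,
       implied_mean_weight_kg = total_iv_mg / per_kg)
}

per_kg_dose_total <- function(cycle_counts, schedule = dose_schedule()) {
  counts <- c(weekly_loading = 0, weekly_maintenance = 0,
              q3w_loading = 0, q3w_maintenance = 0)
  if (any(!names(cycle_counts) %in% names(counts))) {
    rlang::abort("unknown cycle count name",
                 class = "trastucost_domain_error")
  }
  counts[names(cycle_counts)] <- cycle_counts
  if (any(counts < 0)) {
    rlang::abort("cycle counts must be non-negative",
                 class = "trastucost_domain_error")
  }
  sum(counts * c(schedule$weekly_loading_mg_per_kg,
                 schedule$weekly_maintenance_mg_per_kg,
                 schedule$q3w_loading_mg_per_kg,
                 schedule$q3w_maintenance_mg_per_kg))
}

#' Affine cost-versus-mean-weight curve for one scenario
#'
#' With the cycle structure frozen, drug and waste costs of intravenous
#' cycles scale linearly with mean body weight while subcutaneous drug,
#' preparation labour and clinic occupancy do not. The scenario's total cost
#' is therefore affine in mean weight: slope = intravenous price x per-kg
#' dose total x (1 + waste fraction); intercept = subcutaneous drug +
#' preparation + clinic totals. A scenario with no intravenous cycles (all
#' subcutaneous) has slope zero.
#'
#' @param scenario Scenario id the curve describes.
#' @param cycle_structure List with `iv_counts` (named counts as in
#'   [calibrate_per_kg()]; may be empty or zero) and `sc_cycles` (count of
#'   subcutaneous cycles).
#' @param schedule A [dose_schedule()].
#' @param costs A [unit_costs()].
#' @param validity_range_kg Weight range over which the linearization is
#'   read, kg.
#' @return A `cost_curve` object: `scenario`, `slope_eur_per_kg`,
#'   `intercept_eur`, `validity_range_kg`.
#' @export
cost_curve <- function(scenario, cycle_structure, schedule = dose_schedule(),
                       costs = unit_costs(), validity_range_kg = c(40, 100)) {
  iv_counts <- cycle_structure$iv_counts %||% numeric(0)
  sc_cycles <- cycle_structure$sc_cycles %||% 0
  per_kg <- if (length(iv_counts) > 0) {
    per_kg_dose_total(iv_counts, schedule)
  } else 0
  slope <- costs$iv_eur_per_mg * per_kg * (1 + costs$waste_fraction)

  n_iv <- sum(iv_counts)
  n_iv_loading <- sum(iv_counts[grepl("_loading$", names(iv_counts))])
  admin_hours <-
    (n_iv_loading * costs$admin_minutes[["iv_loading"]] +
       (n_iv - n_iv_loading) * costs$admin_minutes[["iv_maintenance"]] +
       sc_cycles * costs$admin_minutes[["sc"]]) / 60
  intercept <- sc_cycles * schedule$sc_fixed_mg * costs$sc_eur_per_mg +
    n_iv * costs$prep_cost_iv_per_cycle_eur +
    sc_cycles * costs$prep_cost_sc_per_cycle_eur +
    admin_hours * costs$clinic_eur_per_hour

  structure(list(scenario = as.integer(scenario),
                 slope_eur_per_kg = slope,
                 intercept_eur = intercept,
                 validity_range_kg = validity_range_kg),
            class = "cost_curve")
}

#' Break-even weight of two affine cost curves
#'
#' Solves `slope_a w + intercept_a = slope_b w + intercept_b`. Symmetric in
#' its arguments.
#'
#' @param curve_a,curve_b `cost_curve` objects.
#' @return The intersection weight in kg; `NA` for parallel curves with
#'   different intercepts; the shared validity range (length-2 vector) for
#'   identical curves.
#' @export
breakeven_weight <- function(curve_a, curve_b) {
  ds <- curve_a$slope_eur_per_kg - curve_b$slope_eur_per_kg
  di <- curve_b$intercept_eur - curve_a$intercept_eur
  if (ds == 0) {
    if (di == 0) {
      return(range(curve_a$validity_range_kg, curve_b$validity_range_kg))
    }
    return(NA_real_)
  }
  di / ds
}

#' Evaluate cost curves over a weight grid
#'
#' @param curves List of `cost_curve` objects.
#' @param weight_grid Numeric vector of mean weights in kg.
#' @return A tibble `weight_kg`, `scenario`, `total_eur`; empty for an
#'   empty grid.
#' @export
curve_table <- function(curves, weight_grid) {
  purrr::map_dfr(curves, function(cv) {
    tibble::tibble(weight_kg = as.numeric(weight_grid),
                   scenario = cv$scenario,
                   total_eur = cv$slope_eur_per_kg * weight_grid +
                     cv$intercept_eur)
  })
}

#' Fit the two-scenario break-even model
#'
#' Builds the scenario-1 (all intravenous, weight-proportional drug + waste)
#' and scenario-2 (all subcutaneous, weight-independent) affine cost curves
#' from an intravenous cycle structure, total intravenous drug mass and
#' subcutaneous cycle count, and solves for the break-even mean body weight.
#' The per-kg calibration and implied mean weight are retained in the fit.
#'
#' @param iv_counts Named intravenous cycle counts (see
#'   [calibrate_per_kg()]); scenario 1's structure.
#' @param total_iv_mg Total intravenous drug mass (mg) delivered under
#'   scenario 1.
#' @param sc_cycles Subcutaneous cycle count under scenario 2.
#' @param schedule,costs The [dose_schedule()] and [unit_costs()].
#' @param validity_range_kg Weight range for the linearization.
#' @return A `breakeven_model`: `curves` (list of two `cost_curve`s),
#'   `calibration` ([calibrate_per_kg()] output), `breakeven_kg`. Has
#'   `tidy()`, `glance()` and `autoplot()` methods.
#' @export
#' @examples
#' fit <- fit_breakeven(
#'   iv_counts = c(weekly_loading = 53, weekly_maintenance = 490,
#'                 q3w_loading = 32, q3w_maintenance = 717),
#'   total_iv_mg = 372214, sc_cycles = 937
#' )
#' glance(fit)
fit_breakeven <- function(iv_counts, total_iv_mg, sc_cycles,
                          schedule = dose_schedule(), costs = unit_costs(),
                          validity_range_kg = c(40, 100)) {
  calibration <- calibrate_per_kg(iv_counts, schedule, total_iv_mg)
  c1 <- cost_curve(1, list(iv_counts = iv_counts, sc_cycles = 0),
                   schedule, costs, validity_range_kg)
  c2 <- cost_curve(2, list(iv_counts = numeric(0), sc_cycles = sc_cycles),
                   schedule, costs, validity_range_kg)
  structure(list(curves = list(c1, c2), calibration = calibration,
                 breakeven_kg = breakeven_weight(c1, c2)),
            class = "breakeven_model")
}

#' Break-even model from a cohort
#'
#' Convenience wrapper: derives the intravenous cycle structure, total drug
#' mass and subcutaneous cycle count from the cohort via [plan_scenario()],
#' then calls [fit_breakeven()].
#'
#' @param cohort A cohort tibble.
#' @inheritParams fit_breakeven
#' @return A `breakeven_model`.
#' @export
fit_breakeven_cohort <- function(cohort, schedule = dose_schedule(),
                                 costs = unit_costs(),
                                 validity_range_kg = c(40, 100)) {
  p1 <- plan_scenario(cohort, 1, schedule, costs)
  p2 <- plan_scenario(cohort, 2, schedule, costs)
  counts <- p1 |>
    dplyr::count(.data$cadence, .data$role) |>
    dplyr::mutate(key = paste(.data$cadence, .data$role, sep = "_"))
  iv_counts <- stats::setNames(counts$n, counts$key)
  fit_breakeven(iv_counts, sum(p1$dose_mg), nrow(p2),
                schedule, costs, validity_range_kg)
}

#' @export
print.breakeven_model <- function(x, ...) {
  cat("Break-even cost model (affine in mean body weight)\n")
  for (cv in x$curves) {
    cat(sprintf("  scenario %d: %.2f EUR/kg x w + %.2f EUR\n",
                cv$scenario, cv$slope_eur_per_kg, cv$intercept_eur))
  }
  cat(sprintf("  implied mean weight: %.2f kg; break-even at %.2f kg\n",
              x$calibration$implied_mean_weight_kg, x$breakeven_kg[1]))
  invisible(x)
}

#' Curve coefficients of a break-even model
#' @param x A `breakeven_model`.
#' @param ... Unused.
#' @return Tibble with one row per scenario curve.
#' @method tidy breakeven_model
#' @export
tidy.breakeven_model <- function(x, ...) {
  purrr::map_dfr(x$curves, function(cv) {
    tibble::tibble(scenario = cv$scenario,
                   slope_eur_per_kg = cv$slope_eur_per_kg,
                   intercept_eur = cv$intercept_eur,
                   validity_min_kg = cv$validity_range_kg[1],
                   validity_max_kg = cv$validity_range_kg[2])
  })
}

#' One-row summary of a break-even model
#' @param x A `breakeven_model`.
#' @param ... Unused.
#' @return One-row tibble with the break-even weight, the per-kg dose total
#'   and the implied mean weight.
#' @method glance breakeven_model
#' @export
glance.breakeven_model <- function(x, ...) {
  tibble::tibble(
    breakeven_kg = x$breakeven_kg[1],
    per_kg_dose_total = x$calibration$per_kg_dose_total,
    implied_mean_weight_kg = x$calibration$implied_mean_weight_kg
  )
}
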