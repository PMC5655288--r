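# Shared fixtures, built in code.

# cohort of two hand-sized patients: one weekly-then-q3w, one q3w-only
tiny_cohort <- function() {
  tibble::tibble(
    id = c("A", "A", "B"),
    phase_index = c(1L, 2L, 1L),
    cadence = c("weekly", "q3w", "q3w"),
    n_loading = c(1L, 0L, 1L),
    n_maintenance = c(11L, 13L, 16L),
    weight_kg = c(60, 60, 80)
  )
}

# single-patient cohort with one q3w phase
one_patient_cohort <- function(weight = 63.75, n_loading = 1L,
                               n_maintenance = 16L) {
  tibble::tibble(id = "P1", phase_index = 1L, cadence = "q3w",
                 n_loading = n_loading, n_maintenance = n_maintenance,
                 weight_kg = weight)
}

# brute-force per-cycle cost ledger: plain loops, no dplyr, independent of
# evaluate_scenario's aggregation path
ledger_oracle <- function(plans, costs = unit_costs()) {
  ids <- unique(plans$patient_id)
  out <- data.frame(patient_id = ids, drug = 0, waste = 0, prep = 0,
                    clinic = 0)
  for (i in seq_len(nrow(plans))) {
    row <- plans[i, ]
    j <- which(out$patient_id == row$patient_id)
    price <- if (row$formulation == "IV") costs$iv_eur_per_mg else
      costs$sc_eur_per_mg
    drug <- row$dose_mg * price
    out$drug[j] <- out$drug[j] + drug
    if (row$formulation == "IV") {
      out$waste[j] <- out$waste[j] + costs$waste_fraction * drug
    }
    out$prep[j] <- out$prep[j] +
      if (row$formulation == "IV") costs$prep_cost_iv_per_cycle_eur else
        costs$prep_cost_sc_per_cycle_eur
    out$clinic[j] <- out$clinic[j] +
      row$admin_minutes / 60 * costs$clinic_eur_per_hour
  }
  out$global <- out$drug + out$waste + out$prep + out$clinic
  out
}

# the printed-aggregate intravenous cycle structure
reference_counts <- function() {
  c(weekly_loading = 53, weekly_maintenance = 490,
    q3w_loading = 32, q3w_maintenance = 717)
}
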