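#' Plot a break-even cost model
#'
#' Total cost of each scenario as a function of mean body weight, with the
#' break-even weight marked.
#'
#' @param object A `breakeven_model`.
#' @param step Grid step in kg.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot breakeven_model
#' @export
autoplot.breakeven_model <- function(object, step = 0.5, ...) {
  rng <- object$curves[[1]]$validity_range_kg
  grid <- seq(rng[1], rng[2], by = step)
  tab <- curve_table(object$curves, grid) |>
    dplyr::mutate(scenario = factor(paste("Scenario", .data$scenario)))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$weight_kg,
                                         y = .data$total_eur,
                                         colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Mean body weight (kg)", y = "Total cost (EUR)",
                  colour = NULL,
                  title = "Cost versus mean body weight") +
    ggplot2::theme_minimal()
  be <- object$breakeven_kg[1]
  if (is.finite(be) && be >= rng[1] && be <= rng[2]) {
    p <- p +
      ggplot2::geom_vline(xintercept = be, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::annotate("text", x = be, y = min(tab$total_eur),
                        label = sprintf("break-even %.1f kg", be),
                        hjust = -0.05, vjust = 0, size = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked cost-component comparison across scenarios
#'
#' @param results List of `scenario_result` objects.
#' @param per_patient Show mean cost per patient instead of cohort totals.
#' @return A ggplot.
#' @export
plot_scenario_costs <- function(results, per_patient = FALSE) {
  tab <- purrr::map_dfr(results, function(r) {
    t <- r$totals
    if (per_patient) t <- t / r$n_patients
    tibble::tibble(scenario = paste("Scenario", r$scenario),
                   component = factor(c("drug", "waste", "preparation",
                                        "clinic"),
                                      levels = c("clinic", "preparation",
                                                 "waste", "drug")),
                   eur = c(t$drug_eur, t$waste_eur, t$prep_eur,
                           t$clinic_eur))
  })
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$scenario, y = .data$eur,
                                    fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL,
                  y = if (per_patient) "Mean cost per patient (EUR)"
                      else "Total cost (EUR)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
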