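## Daily-budget and prey-equivalent scenario calculator.
##
## Converts hourly energy expenditure rates into daily budgets, corrects
## for assimilation efficiency, and expresses gross intake in prey items
## (default: discarded flatfish of 12-13 cm, 84 kJ per fish).

#' Scenario specification for daily budgets
#'
#' @param hours_colony Hours per day at the colony.
#' @param rate_colony Energy expenditure at the colony (kJ/h).
#' @param hours_away Hours per day away on foraging trips.
#' @param rate_away Energy expenditure away (kJ/h).
#' @param assimilation Assimilation efficiency in (0, 1]; default 0.75.
#' @param prey_energy Energy content per prey item (kJ); default 84.
#' @return A `scenario_spec` list.
#' @examples
#' daily_cost(scenario_spec(14, 33, 10, 100))  # 1462 kJ/day
#' @export
scenario_spec <- function(hours_colony, rate_colony, hours_away, rate_away,
                          assimilation = 0.75, prey_energy = 84) {
  if (hours_colony < 0 || hours_away < 0) stop("hours must be >= 0", call. = FALSE)
  if (hours_colony + hours_away > 24 + 1e-9) {
    stop("hours_colony + hours_away must be <= 24", call. = FALSE)
  }
  if (assimilation <= 0 || assimilation > 1) {
    stop("assimilation must be in (0, 1]", call. = FALSE)
  }
  if (prey_energy <= 0) stop("prey_energy must be > 0", call. = FALSE)
  structure(list(
    hours_colony = hours_colony, rate_colony = rate_colony,
    hours_away = hours_away, rate_away = rate_away,
    assimilation = assimilation, prey_energy = prey_energy
  ), class = "scenario_spec")
}

#' Daily energetic cost under a scenario
#'
#' @param spec A [scenario_spec()].
#' @return Daily cost in kJ/day.
#' @export
daily_cost <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  spec$hours_colony * spec$rate_colony + spec$hours_away * spec$rate_away
}

#' Gross intake and prey items needed for a daily cost
#'
#' Divides net daily expenditure by assimilation efficiency to get gross
#' intake, then expresses it in prey items. Both the gross kJ and the
#' item count are rounded to the nearest integer; the item count is
#' computed from the exact (unrounded) gross intake.
#'
#' @param daily_kJ Net daily cost (kJ/day, >= 0).
#' @param spec A [scenario_spec()].
#' @return List with `gross_kJ` (integer kJ) and `n_prey` (items).
#' @examples
#' prey_equivalents(1462, scenario_spec(14, 33, 10, 100))  # 1949 kJ, 23 fish
#' @export
prey_equivalents <- function(daily_kJ, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (daily_kJ < 0) stop("`daily_kJ` must be >= 0", call. = FALSE)
  gross <- daily_kJ / spec$assimilation
  list(gross_kJ = round(gross), n_prey = round(gross / spec$prey_energy))
}

#' Extra gross intake and prey items between two daily costs
#'
#' @param cost_high_kJ,cost_low_kJ Daily costs (kJ/day), high >= low.
#' @param spec A [scenario_spec()].
#' @return List with `extra_gross_kJ` (integer kJ) and `extra_items`.
#' @examples
#' extra_prey(1462, 1162, scenario_spec(14, 33, 10, 100))  # 400 kJ, 5 fish
#' @export
extra_prey <- function(cost_high_kJ, cost_low_kJ, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (cost_high_kJ < cost_low_kJ) {
    stop("`cost_high_kJ` must be >= `cost_low_kJ`", call. = FALSE)
  }
  extra <- (cost_high_kJ - cost_low_kJ) / spec$assimilation
  list(extra_gross_kJ = round(extra),
       extra_items = round(extra / spec$prey_energy))
}

#' Cost of a hypothetical foraging trip
#'
#' Prices a list of (behavior class, duration) legs with the
#' mass-specific class rates; useful for counterfactuals such as trips
#' to foraging sites at different distances from the colony.
#'
#' @param legs Data frame with columns `class` (one of the four behavior
#'   classes) and `duration_h` (> 0), or an empty data frame (0 kJ).
#' @param mass_g Body mass in grams.
#' @return Trip cost in kJ.
#' @examples
#' legs <- data.frame(class = c("flapping_flight", "terrestrial_movement"),
#'                    duration_h = c(0.5, 1.5))
#' hypothetical_trip_cost(legs, 1000)  # ~180 kJ
#' @export
hypothetical_trip_cost <- function(legs, mass_g) {
  if (nrow(legs) == 0) return(0)
  if (any(legs$duration_h <= 0)) stop("leg durations must be > 0", call. = FALSE)
  rates <- behavior_rates(energetic_profile(mass_g))
  bad <- setdiff(legs$class, names(rates))
  if (length(bad)) stop("unknown behavior class(es): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  sum(legs$duration_h * rates[legs$class])
}

#' Percent contrast in hourly rate between habitat groups
#'
#' Contrast of mean hourly expenditure in the high-caloric habitats
#' (urban, marine) against the low-caloric habitats (intertidal,
#' terrestrial): `100 * (mean(urban, marine) / mean(intertidal,
#' terrestrial) - 1)`.
#'
#' @param rates Named numeric with at least `urban`, `marine`,
#'   `intertidal`, `terrestrial` (kJ/h).
#' @return Percent difference.
#' @examples
#' habitat_rate_contrast(c(urban = 89.41, marine = 100.70,
#'                         intertidal = 69.88, terrestrial = 71.96))  # ~34
#' @export
habitat_rate_contrast <- function(rates) {
  need <- c("urban", "marine", "intertidal", "terrestrial")
  if (!all(need %in% names(rates))) {
    stop("`rates` must name urban, marine, intertidal and terrestrial",
         call. = FALSE)
  }
  100 * (mean(rates[c("urban", "marine")]) /
           mean(rates[c("intertidal", "terrestrial")]) - 1)
}
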