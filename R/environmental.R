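#' Avoided passenger-kilometers of a follow-up appointment
#'
#' A video consultation avoids the round trip between home and clinic:
#' `2 * one_way_distance_km` passenger-kilometers per patient travelling
#' by car.
#'
#' @param one_way_distance_km One-way distance(s), km.
#' @return Passenger-kilometers (numeric).
#' @examples
#' avoided_pkm(37)  # 74 pkm
#' @export
avoided_pkm <- function(one_way_distance_km) {
  if (any(one_way_distance_km < 0, na.rm = TRUE)) {
    stop("distance must be non-negative", call. = FALSE)
  }
  2 * one_way_distance_km
}

new_emissions_result <- function(pkm, model, basis, n_patients = NA_real_) {
  masses <- model$factors * pkm / 1000  # g/pkm * pkm -> grams -> kg
  structure(
    list(
      basis = basis,
      pkm = pkm,
      n_patients = n_patients,
      masses_kg = masses,
      env_cost = model$env_cost_per_pkm * pkm,
      model = model
    ),
    class = "emissions_result"
  )
}

#' Emissions avoided by not travelling
#'
#' Multiplies each pollutant's per-pkm emission factor by the avoided
#' passenger-kilometers: `mass_kg = factor_g_per_pkm * pkm / 1000`, and
#' values the avoided travel at the model's environmental cost per pkm.
#'
#' @param pkm Avoided passenger-kilometers (length 1).
#' @param model An [emission_model()].
#' @param basis Label recording what the pkm figure represents.
#' @param n_patients Optional patient count behind the pkm figure.
#' @return An object of class `emissions_result` with per-pollutant masses
#'   in kg (`masses_kg`), the environmental cost in euros (`env_cost`) and
#'   the pkm input.
#' @examples
#' emissions_saved(avoided_pkm(37))  # 11.248 kg greenhouse gases, EUR 3.73
#' @export
emissions_saved <- function(pkm, model = emission_model(),
                            basis = "per_patient", n_patients = NA_real_) {
  stopifnot(inherits(model, "emission_model"))
  if (!is.numeric(pkm) || length(pkm) != 1L || !is.finite(pkm) || pkm < 0) {
    stop("pkm must be a single non-negative number", call. = FALSE)
  }
  new_emissions_result(pkm, model, basis, n_patients)
}

#' Environmental cost of avoided travel
#'
#' `env_cost_per_pkm * pkm` — the agency damage-cost rate applied to the
#' avoided passenger-kilometers.
#'
#' @inheritParams emissions_saved
#' @return Euros (length 1).
#' @examples
#' environmental_cost(74)  # EUR 3.73 at the 195 EUR/t CO2e preset
#' @export
environmental_cost <- function(pkm, model = emission_model()) {
  stopifnot(inherits(model, "emission_model"))
  if (any(pkm < 0, na.rm = TRUE)) stop("pkm must be non-negative", call. = FALSE)
  model$env_cost_per_pkm * pkm
}

#' Pooled mean one-way distance across arms
#'
#' The n-weighted mean of the two arms' mean distances, the distance a
#' typical substituted appointment avoids; used as the default distance of
#' annual extrapolation scenarios.
#'
#' @param aggregates Named list of the two [arm_aggregate()]s
#'   (`telemedicine`, `control`).
#' @return Kilometers (length 1).
#' @export
pooled_mean_distance <- function(aggregates) {
  ms <- vapply(aggregates, agg_stat, numeric(1),
               variable = "one_way_distance_km", field = "mean")
  ns <- vapply(aggregates, agg_stat, numeric(1),
               variable = "one_way_distance_km", field = "n")
  sum(ms * ns) / sum(ns)
}

#' Annual avoided-travel extrapolation
#'
#' Model calculation scaling per-visit savings to a year of clinic
#' operation: `annual pkm = patients_per_week * weeks_per_year * 2 *
#' mean_one_way_distance_km`, with emissions and environmental cost
#' computed as in [emissions_saved()]. Strictly linear, so doubling the
#' weekly patient count doubles every output exactly.
#'
#' @param scenario An [extrapolation_scenario()].
#' @param model An [emission_model()].
#' @return An `emissions_result` with basis `"annual_scenario"`.
#' @examples
#' sc <- extrapolation_scenario(8, 48, mean_one_way_distance_km = 34.34)
#' annual_extrapolation(sc)
#' @export
annual_extrapolation <- function(scenario, model = emission_model()) {
  stopifnot(inherits(scenario, "extrapolation_scenario"),
            inherits(model, "emission_model"))
  if (scenario$patients_per_week == 0) {
    warning("zero patients per week: annual savings are zero", call. = FALSE)
  }
  pkm <- scenario$annual_patients * 2 * scenario$mean_one_way_distance_km
  out <- new_emissions_result(pkm, model, "annual_scenario",
                              n_patients = scenario$annual_patients)
  out$scenario <- scenario
  out
}

#' @export
print.emissions_result <- function(x, ...) {
  cat(sprintf("Avoided emissions (%s, %.2f pkm", x$basis, x$pkm))
  if (!is.na(x$n_patients)) cat(sprintf(", %g patients", x$n_patients))
  cat(")\n")
  for (nm in names(x$masses_kg)) {
    digits <- if (nm == "particulates") 4 else 3
    cat(sprintf("  %-22s %10.*f kg\n", nm, digits, x$masses_kg[[nm]]))
  }
  cat(sprintf("  environmental cost:    EUR %.2f (at EUR %.5f / pkm)\n",
              x$env_cost, x$model$env_cost_per_pkm))
  invisible(x)
}
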