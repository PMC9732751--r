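#' Unit-cost parameters for the societal cost analysis
#'
#' Bundles the unit costs used to monetize travel, patient time and lost
#' production. Defaults are the German base-case values: EUR 0.30 per
#' kilometer travelled (empirical standard cost), EUR 16.00 per hour of
#' unpaid work / leisure time, a gross hourly wage of EUR 29.48 and an
#' average working day of 6.96 hours across full- and part-time employees.
#' The euro-to-dollar rate is carried for display only and never enters any
#' computation.
#'
#' @param cost_per_km Euros per kilometer of car travel.
#' @param time_value_per_hour Euros per hour of patient time.
#' @param gross_hourly_wage Gross hourly wage in euros, used for production
#'   losses.
#' @param working_hours_per_day Average hours of a working day; one full day
#'   is lost per work absence.
#' @param eur_to_usd Display-only exchange rate (USD per 1 EUR).
#'
#' @return An object of class `cost_parameters`.
#' @examples
#' cost_parameters()
#' cost_parameters(working_hours_per_day = 8.2)  # full-time scenario
#' @export
cost_parameters <- function(cost_per_km = 0.30,
                            time_value_per_hour = 16.00,
                            gross_hourly_wage = 29.48,
                            working_hours_per_day = 6.96,
                            eur_to_usd = 0.97) {
  p <- list(
    cost_per_km = cost_per_km,
    time_value_per_hour = time_value_per_hour,
    gross_hourly_wage = gross_hourly_wage,
    working_hours_per_day = working_hours_per_day,
    eur_to_usd = eur_to_usd
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("cost parameter '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(p, class = "cost_parameters")
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("Unit-cost parameters (societal perspective)\n")
  cat(sprintf("  travel:          EUR %.2f / km (round trip doubled)\n", x$cost_per_km))
  cat(sprintf("  time value:      EUR %.2f / h\n", x$time_value_per_hour))
  cat(sprintf("  gross wage:      EUR %.2f / h x %.2f h/day per absence\n",
              x$gross_hourly_wage, x$working_hours_per_day))
  cat(sprintf("  display rate:    EUR 1 = USD %.2f\n", x$eur_to_usd))
  invisible(x)
}

# carbon-price presets of the German Federal Environment Agency: the low rate
# discounts future welfare, the high rate weights generations equally; each is
# tied to an average car damage cost per passenger-kilometer
.carbon_presets <- data.frame(
  carbon_price = c(195, 680),
  env_cost_per_pkm = c(0.05045, 0.12885)
)

.default_emission_factors <- c(
  greenhouse_gases = 152,
  carbon_monoxide = 0.94,
  volatile_hydrocarbons = 0.15,
  nitrogen_oxides = 0.38,
  particulates = 0.006
)

#' Car emission factors and environmental cost rates
#'
#' Per-pollutant car emission factors in grams per passenger-kilometer (pkm),
#' already normalized to an average occupancy of 1.4 passengers, together
#' with the environmental damage cost per pkm and the carbon price it is
#' published alongside. The two (carbon price, cost-per-pkm) pairs
#' \{195 -> 0.05045, 680 -> 0.12885\} are linked agency presets: overriding
#' one member of a pair without the other triggers a warning, and a carbon
#' price that matches a preset silently brings its companion rate along.
#'
#' @param factors Named numeric vector of g/pkm emission factors; names must
#'   be a subset of the five default pollutants.
#' @param car_occupancy Average passengers per car; provenance metadata only
#'   (the factors are already per-pkm at this occupancy).
#' @param carbon_price_eur_per_tonne_co2e Carbon price in euros per tonne of
#'   CO2 equivalent.
#' @param env_cost_per_pkm Environmental damage cost in euros per pkm; when
#'   `NULL`, resolved from the carbon-price preset.
#'
#' @return An object of class `emission_model`.
#' @examples
#' emission_model()                                       # 195 EUR/t preset
#' emission_model(carbon_price_eur_per_tonne_co2e = 680)  # equal-weight preset
#' @export
emission_model <- function(factors = .default_emission_factors,
                           car_occupancy = 1.4,
                           carbon_price_eur_per_tonne_co2e = 195,
                           env_cost_per_pkm = NULL) {
  if (is.null(names(factors)) ||
      !all(names(factors) %in% names(.default_emission_factors))) {
    stop("unknown pollutant key in emission factors; valid keys: ",
         paste(names(.default_emission_factors), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("emission factors must be positive and finite", call. = FALSE)
  }
  idx <- match(carbon_price_eur_per_tonne_co2e, .carbon_presets$carbon_price)
  if (is.null(env_cost_per_pkm)) {
    if (is.na(idx)) {
      stop("no preset env_cost_per_pkm for carbon price ",
           carbon_price_eur_per_tonne_co2e,
           " EUR/t CO2e; supply env_cost_per_pkm explicitly", call. = FALSE)
    }
    env_cost_per_pkm <- .carbon_presets$env_cost_per_pkm[idx]
  } else if (!is.na(idx) &&
             abs(env_cost_per_pkm - .carbon_presets$env_cost_per_pkm[idx]) > 1e-12) {
    warning("carbon price ", carbon_price_eur_per_tonne_co2e,
            " EUR/t CO2e is a preset but env_cost_per_pkm does not match ",
            "its companion rate (", .carbon_presets$env_cost_per_pkm[idx],
            "); the pair is usually overridden together", call. = FALSE)
  }
  if (!is.finite(env_cost_per_pkm) || env_cost_per_pkm <= 0) {
    stop("env_cost_per_pkm must be positive and finite", call. = FALSE)
  }
  if (!is.finite(car_occupancy) || car_occupancy <= 0) {
    stop("car_occupancy must be positive", call. = FALSE)
  }
  structure(
    list(
      factors = factors,
      car_occupancy = car_occupancy,
      carbon_price_eur_per_tonne_co2e = carbon_price_eur_per_tonne_co2e,
      env_cost_per_pkm = env_cost_per_pkm
    ),
    class = "emission_model"
  )
}

#' @export
print.emission_model <- function(x, ...) {
  cat("Car emission model (per passenger-kilometer, occupancy ",
      x$car_occupancy, ")\n", sep = "")
  for (nm in names(x$factors)) {
    cat(sprintf("  %-22s %8.3f g/pkm\n", nm, x$factors[[nm]]))
  }
  cat(sprintf("  environmental cost: EUR %.5f / pkm (carbon price EUR %g / t CO2e)\n",
              x$env_cost_per_pkm, x$carbon_price_eur_per_tonne_co2e))
  invisible(x)
}

#' Annual extrapolation scenario
#'
#' Defines the model calculation that scales per-visit avoided travel to a
#' year of clinic operation: a weekly number of substituted visits, the
#' number of operating weeks per year (48, i.e. 384 patients at 8 per week),
#' and the mean one-way home-to-clinic distance to assume per patient.
#'
#' @param patients_per_week Video consultations substituted per week.
#' @param weeks_per_year Operating weeks per year.
#' @param mean_one_way_distance_km Mean one-way distance in kilometers,
#'   typically the n-weighted mean of the two arms' distance means (see
#'   [pooled_mean_distance()]).
#'
#' @return An object of class `extrapolation_scenario`.
#' @export
extrapolation_scenario <- function(patients_per_week = 8,
                                   weeks_per_year = 48,
                                   mean_one_way_distance_km) {
  if (!is.finite(patients_per_week) || patients_per_week < 0) {
    stop("patients_per_week must be a non-negative number", call. = FALSE)
  }
  if (!is.finite(weeks_per_year) || weeks_per_year <= 0) {
    stop("weeks_per_year must be positive", call. = FALSE)
  }
  if (!is.finite(mean_one_way_distance_km) || mean_one_way_distance_km < 0) {
    stop("mean_one_way_distance_km must be non-negative", call. = FALSE)
  }
  structure(
    list(
      patients_per_week = patients_per_week,
      weeks_per_year = weeks_per_year,
      annual_patients = patients_per_week * weeks_per_year,
      mean_one_way_distance_km = mean_one_way_distance_km
    ),
    class = "extrapolation_scenario"
  )
}

#' Read analysis parameters from a YAML configuration file
#'
#' The configuration holds optional `cost`, `emission` and `extrapolation`
#' blocks whose keys match the arguments of [cost_parameters()],
#' [emission_model()] and [extrapolation_scenario()]. Every key is optional:
#' an empty (or absent) file yields the base-case defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list with elements `cost`, `emission` and `extrapolation`
#'   (the latter a plain list of overrides, resolved later against the
#'   cohort's pooled mean distance).
#' @export
read_params <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  check_keys <- function(block, fun, label) {
    bad <- setdiff(names(block), names(formals(fun)))
    if (length(bad)) {
      stop("unknown ", label, " parameter(s): ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(names(formals(fun)), collapse = ", "),
           call. = FALSE)
    }
  }
  cost_block <- cfg$cost %||% list()
  emis_block <- cfg$emission %||% list()
  extr_block <- cfg$extrapolation %||% list()
  check_keys(cost_block, cost_parameters, "cost")
  check_keys(emis_block, emission_model, "emission")
  check_keys(extr_block, extrapolation_scenario, "extrapolation")
  if (!is.null(emis_block$factors)) {
    emis_block$factors <- unlist(emis_block$factors)
  }
  list(
    cost = do.call(cost_parameters, cost_block),
    emission = do.call(emission_model, emis_block),
    extrapolation = extr_block
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
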