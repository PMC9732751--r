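.cost_keys <- c("cost_per_km", "time_value_per_hour", "gross_hourly_wage",
                "working_hours_per_day", "eur_to_usd")
.emission_keys <- c("carbon_price_eur_per_tonne_co2e", "env_cost_per_pkm",
                    "factors", "car_occupancy")
.extrap_keys <- c("patients_per_week", "weeks_per_year",
                  "mean_one_way_distance_km")

#' Define a deterministic sensitivity scenario
#'
#' A named set of parameter overrides applied on top of the base case.
#' Valid keys are the arguments of [cost_parameters()],
#' [emission_model()] and [extrapolation_scenario()]; an unknown key is an
#' error listing the valid ones.
#'
#' @param name Scenario label.
#' @param ... Named overrides, e.g. `working_hours_per_day = 8.2`.
#' @return An object of class `scenario`.
#' @examples
#' scenario("full_time", working_hours_per_day = 8.2)
#' @export
scenario <- function(name, ...) {
  overrides <- list(...)
  valid <- c(.cost_keys, .emission_keys, .extrap_keys)
  bad <- setdiff(names(overrides), valid)
  if (length(bad) || (length(overrides) && is.null(names(overrides)))) {
    stop("unknown scenario override key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, overrides = overrides), class = "scenario")
}

#' The standard sensitivity scenarios
#'
#' The four deterministic scenarios of the base analysis: full-time (8.2 h)
#' and part-time (3.9 h) working days for the production-loss valuation,
#' the equal-generational-weight carbon price (680 EUR/t CO2e with its
#' companion rate of 0.12885 EUR/pkm), and a doubled weekly volume of 16
#' substituted consultations.
#'
#' @return A named list of [scenario()] objects.
#' @export
default_scenarios <- function() {
  list(
    full_time = scenario("full_time", working_hours_per_day = 8.2),
    part_time = scenario("part_time", working_hours_per_day = 3.9),
    equal_weight_carbon = scenario("equal_weight_carbon",
                                   carbon_price_eur_per_tonne_co2e = 680,
                                   env_cost_per_pkm = 0.12885),
    sixteen_per_week = scenario("sixteen_per_week", patients_per_week = 16)
  )
}

#' Run the base-case societal analysis
#'
#' End-to-end pipeline: arm summaries of the questionnaire variables
#' (with Mann-Whitney p-values on patient-level input), the cost table
#' with between-arm differences and totals by employment status, the
#' avoided-emission table for the telemedicine arm, and the annual
#' extrapolation. Accepts either a patient-level cohort (both arms
#' required) or the pair of published arm aggregates from
#' [reference_summary()]; thanks to the linearity of every cost and
#' emission in its input, both routes give identical arm-level results.
#' Output is deterministic for identical input and parameters.
#'
#' @param x A validated cohort tibble containing both arms, or a named
#'   list of two [arm_aggregate()]s (`telemedicine`, `control`).
#' @param params A [cost_parameters()] object.
#' @param emodel An [emission_model()] object.
#' @param patients_per_week,weeks_per_year Annual extrapolation settings;
#'   the scenario distance defaults to the pooled mean one-way distance of
#'   the two arms.
#' @return An object of class `analysis_report` with elements `table1`
#'   (patient-level input only), `table2`, `table3`, `table4`, `totals`,
#'   `annual`, `difference`, the underlying summaries, and `metadata`.
#' @examples
#' rep <- run_base_case(reference_summary())
#' rep$totals
#' @export
run_base_case <- function(x, params = cost_parameters(),
                          emodel = emission_model(),
                          patients_per_week = 8, weeks_per_year = 48) {
  if (is.data.frame(x)) {
    cohort <- validate_cohort(x)
    present <- unique(cohort$arm)
    if (!all(.arms %in% present)) {
      stop("cohort must contain both arms; found only: ",
           paste(present, collapse = ", "), call. = FALSE)
    }
    aggregates <- setNames(lapply(.arms, aggregate_arm, cohort = cohort), .arms)
    table1 <- build_table1(cohort)
    table2 <- build_table2(aggregates, cohort)
    input <- "cohort"
  } else if (is.list(x) && all(.arms %in% names(x)) &&
             all(vapply(x[.arms], inherits, logical(1), "arm_aggregate"))) {
    cohort <- NULL
    aggregates <- x[.arms]
    table1 <- NULL
    table2 <- build_table2(aggregates, NULL)
    input <- "aggregate"
  } else {
    stop("x must be a cohort data frame or a named list of two arm aggregates",
         call. = FALSE)
  }

  summaries <- list(
    telemedicine = arm_cost_summary(aggregates$telemedicine, params),
    control = arm_cost_summary(aggregates$control, params)
  )
  diff <- cost_difference(summaries$telemedicine, summaries$control)
  env <- build_environment(aggregates, cohort, emodel)
  extrap <- extrapolation_scenario(
    patients_per_week, weeks_per_year,
    mean_one_way_distance_km = pooled_mean_distance(aggregates)
  )
  annual <- annual_extrapolation(extrap, emodel)

  structure(
    list(
      table1 = table1,
      table2 = table2,
      table3 = build_table3(summaries, diff),
      table4 = build_table4(env),
      totals = build_totals(summaries, diff),
      annual = annual,
      difference = diff,
      summaries = summaries,
      aggregates = aggregates,
      emissions = env,
      metadata = list(
        input = input,
        n_per_arm = vapply(aggregates, `[[`, numeric(1), "n_records"),
        params = unclass(params),
        emission_model = list(
          factors = as.list(emodel$factors),
          car_occupancy = emodel$car_occupancy,
          carbon_price_eur_per_tonne_co2e = emodel$carbon_price_eur_per_tonne_co2e,
          env_cost_per_pkm = emodel$env_cost_per_pkm
        ),
        extrapolation = list(patients_per_week = patients_per_week,
                             weeks_per_year = weeks_per_year,
                             mean_one_way_distance_km = extrap$mean_one_way_distance_km),
        version = as.character(packageVersion("telecost"))
      ),
      params = params,
      emodel = emodel,
      extrap = extrap
    ),
    class = "analysis_report"
  )
}

build_table1 <- function(cohort) {
  characteristic <- function(label, values) {
    keep <- !is.na(values)
    tab <- table(values[keep], cohort$arm[keep])[, .arms, drop = FALSE]
    # a characteristic with a single observed level carries no contrast
    p <- if (nrow(tab) >= 2) fisher.test(t(tab))$p.value else NA_real_
    tibble(
      characteristic = label,
      category = rownames(tab),
      telemedicine_n = as.integer(tab[, "telemedicine"]),
      telemedicine_pct = round(100 * tab[, "telemedicine"] /
                                 sum(tab[, "telemedicine"])),
      control_n = as.integer(tab[, "control"]),
      control_pct = round(100 * tab[, "control"] / sum(tab[, "control"])),
      p_value = p
    )
  }
  out <- rbind(
    characteristic("indication", cohort$indication),
    characteristic("age_band", factor(cohort$age_band, levels = .age_bands)),
    characteristic("sex", cohort$sex),
    characteristic("employed", ifelse(cohort$employed, "yes", "no"))
  )
  tibble::remove_rownames(out)
}

build_table2 <- function(aggregates, cohort) {
  tele <- aggregates$telemedicine$stats
  ctrl <- aggregates$control$stats
  out <- tibble(
    variable = tele$variable,
    telemedicine_n = tele$n, telemedicine_mean = tele$mean,
    telemedicine_sd = tele$sd, telemedicine_median = tele$median,
    telemedicine_q1 = tele$q1, telemedicine_q3 = tele$q3,
    control_n = ctrl$n, control_mean = ctrl$mean, control_sd = ctrl$sd,
    control_median = ctrl$median, control_q1 = ctrl$q1, control_q3 = ctrl$q3
  )
  out$p_value <- if (is.null(cohort)) NA_real_ else {
    vapply(out$variable, function(v) {
      xs <- cohort[[v]][cohort$arm == "telemedicine"]
      ys <- cohort[[v]][cohort$arm == "control"]
      mann_whitney(xs[!is.na(xs)], ys[!is.na(ys)])$p_value
    }, numeric(1))
  }
  out
}

build_table3 <- function(summaries, diff) {
  labels <- c(travel_cost = "Travel costs",
              travel_time_cost = "Travel time costs",
              waiting_time_cost = "Waiting time costs",
              total_time_cost = "Total time costs")
  tm <- summaries$telemedicine$components
  cm <- summaries$control$components
  r2 <- function(x) round(x, 2)
  comp <- tibble(
    component = unname(labels[tm$component]),
    telemedicine_mean = tm$mean, telemedicine_sd = tm$sd,
    control_mean = cm$mean, control_sd = cm$sd,
    difference = r2(cm$mean) - r2(tm$mean)
  )
  prod <- tibble(
    component = "Production loss",
    telemedicine_mean = summaries$telemedicine$production$total,
    telemedicine_sd = NA_real_,
    control_mean = summaries$control$production$total,
    control_sd = NA_real_,
    difference = r2(summaries$control$production$total) -
      r2(summaries$telemedicine$production$total)
  )
  rbind(comp, prod)
}

build_totals <- function(summaries, diff) {
  do.call(rbind, lapply(.arms, function(a) {
    s <- summaries[[a]]
    tibble(arm = a, employment = s$totals$employment,
           total = s$totals$total,
           total_rounded_components = s$totals$total_rounded_components)
  }))
}

build_environment <- function(aggregates, cohort, emodel) {
  if (is.null(cohort)) {
    # published aggregates carry no transport-mode breakdown; use the
    # full-arm mean distance
    mean_dist <- agg_stat(aggregates$telemedicine, "one_way_distance_km", "mean")
    n <- aggregates$telemedicine$n_records
  } else {
    tele <- cohort[cohort$arm == "telemedicine" &
                     cohort$transport_mode == "car" &
                     !is.na(cohort$one_way_distance_km), ]
    if (nrow(tele) == 0L) stop("no telemedicine car records with distances",
                               call. = FALSE)
    mean_dist <- mean(tele$one_way_distance_km)
    n <- nrow(tele)
  }
  per_patient <- emissions_saved(avoided_pkm(mean_dist), emodel,
                                 basis = "per_patient", n_patients = 1)
  total <- emissions_saved(avoided_pkm(mean_dist) * n, emodel,
                           basis = "cohort_total", n_patients = n)
  list(per_patient = per_patient, total = total)
}

build_table4 <- function(env) {
  tibble(
    quantity = c(names(env$per_patient$masses_kg), "environmental_cost_eur"),
    per_patient = c(unname(env$per_patient$masses_kg), env$per_patient$env_cost),
    total = c(unname(env$total$masses_kg), env$total$env_cost)
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Societal-perspective analysis report (",
      x$metadata$input, " input; n = ",
      paste(x$metadata$n_per_arm, collapse = " + "), ")\n", sep = "")
  cat("\nCosts per appointment (euros):\n")
  df <- as.data.frame(x$table3)
  df[-1] <- lapply(df[-1], function(v) round(v, 2))
  print(df, row.names = FALSE)
  cat(sprintf("\nHeadline saving per employed patient: EUR %.2f\n",
              x$difference$saving_employed))
  cat(sprintf("Avoided greenhouse gases per patient: %.3f kg (EUR %.2f environmental cost)\n",
              x$emissions$per_patient$masses_kg[["greenhouse_gases"]],
              x$emissions$per_patient$env_cost))
  invisible(x)
}

#' Run deterministic sensitivity scenarios
#'
#' Re-runs only the stage of the base-case report each scenario touches:
#' cost overrides recompute the cost table and totals (the emission tables
#' are untouched), emission overrides recompute the emission and annual
#' tables (costs untouched), extrapolation overrides recompute the annual
#' table only. The base-case report is never modified.
#'
#' @param report An [run_base_case()] report.
#' @param scenarios A list of [scenario()] objects.
#' @return A named list of `scenario_result` objects, each holding the
#'   scenario, which stages it affected, and the recomputed tables.
#' @examples
#' rep <- run_base_case(reference_summary())
#' res <- run_scenarios(rep, default_scenarios())
#' res$full_time$totals
#' @export
run_scenarios <- function(report, scenarios) {
  stopifnot(inherits(report, "analysis_report"))
  if (!length(scenarios)) return(list())
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  out <- lapply(scenarios, function(sc) run_one_scenario(report, sc))
  setNames(out, vapply(out, `[[`, character(1), "name"))
}

run_one_scenario <- function(report, sc) {
  stopifnot(inherits(sc, "scenario"))
  ov <- sc$overrides
  affected <- character()
  res <- list(name = sc$name, overrides = ov)

  params <- report$params
  emodel <- report$emodel
  extrap <- report$extrap

  if (any(names(ov) %in% .cost_keys)) {
    affected <- c(affected, "costs")
    params <- do.call(cost_parameters,
                      modifyList(unclass(report$params), ov[names(ov) %in% .cost_keys]))
    summaries <- list(
      telemedicine = arm_cost_summary(report$aggregates$telemedicine, params),
      control = arm_cost_summary(report$aggregates$control, params)
    )
    diff <- cost_difference(summaries$telemedicine, summaries$control)
    res$table3 <- build_table3(summaries, diff)
    res$totals <- build_totals(summaries, diff)
    res$difference <- diff
    res$summaries <- summaries
  }
  if (any(names(ov) %in% .emission_keys)) {
    affected <- c(affected, "emissions", "annual")
    base <- report$metadata$emission_model
    eargs <- modifyList(
      list(factors = unlist(base$factors), car_occupancy = base$car_occupancy,
           carbon_price_eur_per_tonne_co2e = base$carbon_price_eur_per_tonne_co2e,
           env_cost_per_pkm = base$env_cost_per_pkm),
      ov[names(ov) %in% .emission_keys]
    )
    if ("carbon_price_eur_per_tonne_co2e" %in% names(ov) &&
        !("env_cost_per_pkm" %in% names(ov))) {
      # linked preset: let the constructor resolve the companion rate
      eargs$env_cost_per_pkm <- NULL
    }
    emodel <- do.call(emission_model, eargs)
    per_patient <- emissions_saved(report$emissions$per_patient$pkm, emodel,
                                   basis = "per_patient", n_patients = 1)
    total <- emissions_saved(report$emissions$total$pkm, emodel,
                             basis = "cohort_total",
                             n_patients = report$emissions$total$n_patients)
    res$table4 <- build_table4(list(per_patient = per_patient, total = total))
    res$emissions <- list(per_patient = per_patient, total = total)
  }
  if (any(names(ov) %in% c(.extrap_keys, .emission_keys))) {
    if (any(names(ov) %in% .extrap_keys)) affected <- c(affected, "annual")
    extrap <- extrapolation_scenario(
      ov$patients_per_week %||% extrap$patients_per_week,
      ov$weeks_per_year %||% extrap$weeks_per_year,
      ov$mean_one_way_distance_km %||% extrap$mean_one_way_distance_km
    )
    res$annual <- annual_extrapolation(extrap, emodel)
  }
  res$affected <- unique(affected)
  structure(res, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario '", x$name, "' (affects: ",
      paste(x$affected, collapse = ", "), ")\n", sep = "")
  for (nm in names(x$overrides)) {
    cat("  ", nm, " = ", format(x$overrides[[nm]]), "\n", sep = "")
  }
  if (!is.null(x$totals)) {
    cat("  totals by employment status (rounded components):\n")
    print(as.data.frame(x$totals), row.names = FALSE)
  }
  if (!is.null(x$annual)) {
    cat(sprintf("  annual greenhouse gases: %.2f kg, environmental cost EUR %.2f\n",
                x$annual$masses_kg[["greenhouse_gases"]], x$annual$env_cost))
  }
  invisible(x)
}
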