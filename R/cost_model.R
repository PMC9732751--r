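.cost_components <- c("travel_cost", "travel_time_cost",
                      "waiting_time_cost", "total_time_cost")

#' Travel cost of one follow-up appointment
#'
#' Values the round trip between home and clinic at the per-kilometer rate:
#' `cost_per_km * 2 * one_way_distance_km`. Control-arm patients incur this
#' cost; telemedicine patients incur an actual cost of zero, and the same
#' formula is returned as the counterfactual cost they avoided. Missing
#' distances propagate as missing results.
#'
#' @param one_way_distance_km One-way home-to-clinic distance(s), km.
#' @param params A [cost_parameters()] object.
#' @param arm `"control"` or `"telemedicine"`.
#' @return A tibble with columns `actual` and `counterfactual` (euros).
#' @examples
#' travel_cost(31.58, cost_parameters(), "control")       # EUR 18.95
#' travel_cost(37.00, cost_parameters(), "telemedicine")  # 0 / EUR 22.20
#' @export
travel_cost <- function(one_way_distance_km, params = cost_parameters(),
                        arm = c("control", "telemedicine")) {
  arm <- match.arg(arm)
  stopifnot(inherits(params, "cost_parameters"))
  if (any(one_way_distance_km < 0, na.rm = TRUE)) {
    stop("distance must be non-negative", call. = FALSE)
  }
  round_trip <- params$cost_per_km * 2 * one_way_distance_km
  if (arm == "control") {
    tibble(actual = round_trip, counterfactual = round_trip)
  } else {
    tibble(actual = ifelse(is.na(round_trip), NA_real_, 0),
           counterfactual = round_trip)
  }
}

#' Monetary value of patient time
#'
#' Values a duration at the fixed hourly rate for unpaid work and leisure
#' time: `time_value_per_hour * minutes / 60`. Applied downstream to
#' waiting time, to round-trip travel time (two times the one-way time) and
#' to the total time spent on the appointment.
#'
#' @param duration_min Duration(s) in minutes.
#' @param params A [cost_parameters()] object.
#' @return Euros (numeric, same length as input).
#' @examples
#' time_cost(154.80)  # EUR 41.28
#' time_cost(60)      # the hourly rate itself
#' @export
time_cost <- function(duration_min, params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  if (any(duration_min < 0, na.rm = TRUE)) {
    stop("duration must be non-negative", call. = FALSE)
  }
  params$time_value_per_hour * duration_min / 60
}

#' Production loss of one work absence
#'
#' Human-capital valuation of one full working day lost per absent
#' patient: `gross_hourly_wage * working_hours_per_day`.
#'
#' @param params A [cost_parameters()] object.
#' @return Euros (length 1).
#' @examples
#' production_loss_per_absence()  # EUR 205.18 at the base-case wage/hours
#' @export
production_loss_per_absence <- function(params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  params$gross_hourly_wage * params$working_hours_per_day
}

#' Arm-level production loss
#'
#' Total and per-employed-patient production loss for one arm, with the SD
#' taken over the employed patients' individual losses (each absence costs
#' one full working day, everyone else zero).
#'
#' @param n_absent Employed patients absent from work.
#' @param n_employed Employed patients in the arm (>= 1).
#' @param params A [cost_parameters()] object.
#' @return A list with `total`, `mean_per_employed`, `sd_per_employed` (euros).
#' @examples
#' arm_production_loss(1, 20)  # EUR 205.18 total, EUR 10.26 per employed
#' @export
arm_production_loss <- function(n_absent, n_employed,
                                params = cost_parameters()) {
  if (n_employed < 1) {
    stop("mean production loss per employed patient is undefined for ",
         "n_employed = 0", call. = FALSE)
  }
  if (n_absent < 0 || n_absent > n_employed) {
    stop("need 0 <= n_absent <= n_employed", call. = FALSE)
  }
  loss <- production_loss_per_absence(params)
  total <- n_absent * loss
  mean_pe <- total / n_employed
  sd_pe <- if (n_employed > 1) {
    sqrt((n_absent * (loss - mean_pe)^2 +
            (n_employed - n_absent) * mean_pe^2) / (n_employed - 1))
  } else 0
  list(total = total, mean_per_employed = mean_pe, sd_per_employed = sd_pe)
}

#' Per-patient cost table
#'
#' Computes the three societal cost components for every patient: travel
#' cost (round trip, zero actual for the telemedicine arm with the avoided
#' cost kept as a counterfactual), time costs of travel, waiting and total
#' appointment time, and the production loss of a work absence. Missing
#' questionnaire items propagate as missing costs and are excluded from
#' arm-level aggregation per component.
#'
#' @param cohort A validated cohort tibble.
#' @param params A [cost_parameters()] object.
#' @return A tibble, one row per patient, with the component costs and the
#'   two totals bases (`total_cost_unemployed_basis` = travel + total time;
#'   `total_cost_employed_basis` adds the patient's production loss).
#' @export
patient_costs <- function(cohort, params = cost_parameters()) {
  cohort <- validate_cohort(cohort)
  tele <- cohort$arm == "telemedicine"
  rt <- params$cost_per_km * 2 * cohort$one_way_distance_km
  travel <- ifelse(tele, ifelse(is.na(rt), NA_real_, 0), rt)
  travel_cf <- rt
  tt <- time_cost_allow_na(2 * cohort$travel_time_min, params)
  travel_time <- ifelse(tele, ifelse(is.na(tt), NA_real_, 0), tt)
  travel_time_cf <- tt
  waiting <- time_cost_allow_na(cohort$waiting_time_min, params)
  total_time <- time_cost_allow_na(cohort$total_time_min, params)
  loss <- ifelse(is.na(cohort$absent_from_work), NA_real_,
                 ifelse(cohort$absent_from_work,
                        production_loss_per_absence(params), 0))
  unemp <- travel + total_time
  tibble(
    patient_id = cohort$patient_id,
    arm = cohort$arm,
    employed = cohort$employed,
    absent_from_work = cohort$absent_from_work,
    travel_cost = travel,
    travel_cost_counterfactual = travel_cf,
    travel_time_cost = travel_time,
    travel_time_cost_counterfactual = travel_time_cf,
    waiting_time_cost = waiting,
    total_time_cost = total_time,
    production_loss = loss,
    total_cost_unemployed_basis = unemp,
    total_cost_employed_basis = unemp + loss
  )
}

time_cost_allow_na <- function(duration_min, params) {
  out <- rep(NA_real_, length(duration_min))
  ok <- !is.na(duration_min)
  out[ok] <- time_cost(duration_min[ok], params)
  out
}

#' Arm-level cost summary
#'
#' Builds the cost table for one arm: mean and SD of each cost component,
#' counterfactual (avoided) travel and travel-time costs for the
#' telemedicine arm, arm production loss, and totals by employment status.
#' Because every cost is linear in its input, the summary can be computed
#' either from patient-level records or directly from an [arm_aggregate()]
#' of published group means — both routes agree.
#'
#' Totals follow the composition `unemployed = travel + total time` and
#' `employed = unemployed + mean production loss per employed patient`;
#' travel-time and waiting-time costs are reported separately but not
#' added, since they are already contained in the total time spent on the
#' appointment. Each total is exposed at full precision and as the sum of
#' its components rounded to cents (the convention used in published cost
#' tables).
#'
#' @param x A validated cohort tibble or an [arm_aggregate()].
#' @param ... Passed on to methods.
#' @return An object of class `arm_cost_summary`.
#' @examples
#' ref <- reference_summary()
#' arm_cost_summary(ref$control)
#' @export
arm_cost_summary <- function(x, ...) UseMethod("arm_cost_summary")

#' @rdname arm_cost_summary
#' @param params A [cost_parameters()] object.
#' @export
arm_cost_summary.arm_aggregate <- function(x, params = cost_parameters(), ...) {
  tele <- x$arm == "telemedicine"
  scale_stat <- function(variable, factor) {
    c(mean = factor * agg_stat(x, variable, "mean"),
      sd = factor * agg_stat(x, variable, "sd"))
  }
  ckm2 <- params$cost_per_km * 2
  tph <- params$time_value_per_hour
  travel <- scale_stat("one_way_distance_km", ckm2)
  travel_time <- scale_stat("travel_time_min", 2 * tph / 60)
  waiting <- scale_stat("waiting_time_min", tph / 60)
  total_time <- scale_stat("total_time_min", tph / 60)
  comp <- tibble(
    component = .cost_components,
    mean = c(if (tele) 0 else travel[["mean"]],
             if (tele) 0 else travel_time[["mean"]],
             waiting[["mean"]], total_time[["mean"]]),
    sd = c(if (tele) 0 else travel[["sd"]],
           if (tele) 0 else travel_time[["sd"]],
           waiting[["sd"]], total_time[["sd"]]),
    counterfactual_mean = c(travel[["mean"]], travel_time[["mean"]], NA, NA)
  )
  new_arm_cost_summary(x$arm, x$n_records, comp,
                       x$n_absent, x$n_employed, params)
}

#' @rdname arm_cost_summary
#' @param arm Which arm to summarize when `x` is a cohort.
#' @export
arm_cost_summary.data.frame <- function(x, arm = .arms,
                                        params = cost_parameters(), ...) {
  arm <- match.arg(arm)
  pc <- patient_costs(x, params)
  pc <- pc[pc$arm == arm, ]
  if (nrow(pc) == 0L) stop("no records in arm '", arm, "'", call. = FALSE)
  mstat <- function(col) {
    v <- pc[[col]][!is.na(pc[[col]])]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else 0)
  }
  tr <- mstat("travel_cost"); trc <- mstat("travel_cost_counterfactual")
  tt <- mstat("travel_time_cost"); ttc <- mstat("travel_time_cost_counterfactual")
  wt <- mstat("waiting_time_cost"); to <- mstat("total_time_cost")
  comp <- tibble(
    component = .cost_components,
    mean = c(tr[["mean"]], tt[["mean"]], wt[["mean"]], to[["mean"]]),
    sd = c(tr[["sd"]], tt[["sd"]], wt[["sd"]], to[["sd"]]),
    counterfactual_mean = c(trc[["mean"]], ttc[["mean"]], NA, NA)
  )
  n_employed <- sum(pc$employed, na.rm = TRUE)
  n_absent <- sum(pc$absent_from_work, na.rm = TRUE)
  new_arm_cost_summary(arm, nrow(pc), comp, n_absent, n_employed, params)
}

new_arm_cost_summary <- function(arm, n_records, components,
                                 n_absent, n_employed, params) {
  prod <- arm_production_loss(n_absent, max(n_employed, 1L), params)
  if (n_employed < 1) prod <- list(total = 0, mean_per_employed = NA_real_,
                                   sd_per_employed = NA_real_)
  cm <- setNames(components$mean, components$component)
  unemp <- cm[["travel_cost"]] + cm[["total_time_cost"]]
  emp <- unemp + prod$mean_per_employed
  r2 <- function(x) round(x, 2)
  totals <- tibble(
    employment = c("employed", "unemployed"),
    total = c(emp, unemp),
    total_rounded_components = c(
      r2(cm[["travel_cost"]]) + r2(cm[["total_time_cost"]]) +
        r2(prod$mean_per_employed),
      r2(cm[["travel_cost"]]) + r2(cm[["total_time_cost"]])
    )
  )
  structure(
    list(
      arm = arm, n_records = n_records, components = components,
      production = c(prod, list(n_absent = n_absent, n_employed = n_employed,
                                per_absence = production_loss_per_absence(params))),
      totals = totals, params = params
    ),
    class = "arm_cost_summary"
  )
}

#' @export
print.arm_cost_summary <- function(x, ...) {
  cat(sprintf("Cost summary: %s arm (n = %d)\n", x$arm, x$n_records))
  df <- as.data.frame(x$components)
  df[-1] <- lapply(df[-1], function(v) round(v, 2))
  print(df, row.names = FALSE)
  cat(sprintf("  production loss: total EUR %.2f, mean EUR %.2f per employed (%d absent / %d employed)\n",
              x$production$total, x$production$mean_per_employed,
              x$production$n_absent, x$production$n_employed))
  cat(sprintf("  total per employed patient:   EUR %.2f\n",
              x$totals$total_rounded_components[1]))
  cat(sprintf("  total per unemployed patient: EUR %.2f\n",
              x$totals$total_rounded_components[2]))
  invisible(x)
}

#' Total cost of one follow-up appointment
#'
#' Reads the employment-specific total off an [arm_cost_summary()]:
#' mean travel cost plus mean total-time cost, plus (for employed patients)
#' the mean production loss per employed patient.
#'
#' @param summary An [arm_cost_summary()].
#' @param employment `"employed"` or `"unemployed"`.
#' @param rounded If `TRUE` (default), sum components rounded to cents, the
#'   convention of published cost tables; if `FALSE`, full precision.
#' @return Euros (length 1).
#' @examples
#' total_cost_per_patient(arm_cost_summary(reference_summary()$control),
#'                        "employed")  # EUR 92.63
#' @export
total_cost_per_patient <- function(summary,
                                   employment = c("employed", "unemployed"),
                                   rounded = TRUE) {
  stopifnot(inherits(summary, "arm_cost_summary"))
  employment <- match.arg(employment)
  col <- if (rounded) "total_rounded_components" else "total"
  summary$totals[[col]][summary$totals$employment == employment]
}

#' Between-arm cost differences
#'
#' Control-minus-telemedicine differences for every cost component, the arm
#' production losses, and the totals by employment status. The headline
#' saving is the employed-patient total difference. Both summaries must
#' have been computed under identical unit-cost parameters.
#'
#' @param tele,control [arm_cost_summary()] objects for the two arms.
#' @return An object of class `cost_difference` with tibbles `components`
#'   and `totals` plus the scalar `saving_employed` (rounded-component
#'   scale) and `saving_unemployed`.
#' @examples
#' ref <- reference_summary()
#' cost_difference(arm_cost_summary(ref$telemedicine),
#'                 arm_cost_summary(ref$control))
#' @export
cost_difference <- function(tele, control) {
  stopifnot(inherits(tele, "arm_cost_summary"),
            inherits(control, "arm_cost_summary"))
  if (tele$arm != "telemedicine" || control$arm != "control") {
    stop("pass the telemedicine summary first, the control summary second",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(unclass(tele$params), unclass(control$params)))) {
    stop("arm summaries were computed under different cost parameters",
         call. = FALSE)
  }
  comp <- tibble(
    component = c(.cost_components, "production_loss_total",
                  "production_loss_mean_per_employed"),
    telemedicine = c(tele$components$mean, tele$production$total,
                     tele$production$mean_per_employed),
    control = c(control$components$mean, control$production$total,
                control$production$mean_per_employed)
  )
  comp$difference <- comp$control - comp$telemedicine
  tele_tot <- tele$totals; ctrl_tot <- control$totals
  totals <- tibble(
    employment = c("employed", "unemployed"),
    telemedicine = tele_tot$total_rounded_components,
    control = ctrl_tot$total_rounded_components,
    difference = ctrl_tot$total_rounded_components -
      tele_tot$total_rounded_components,
    difference_full = ctrl_tot$total - tele_tot$total
  )
  structure(
    list(
      components = comp, totals = totals,
      saving_employed = totals$difference[totals$employment == "employed"],
      saving_unemployed = totals$difference[totals$employment == "unemployed"]
    ),
    class = "cost_difference"
  )
}

#' @export
print.cost_difference <- function(x, ...) {
  cat("Cost difference (control - telemedicine), euros\n")
  df <- as.data.frame(x$components)
  df[-1] <- lapply(df[-1], function(v) round(v, 2))
  print(df, row.names = FALSE)
  cat(sprintf("  saving per employed patient:   EUR %.2f\n", x$saving_employed))
  cat(sprintf("  saving per unemployed patient: EUR %.2f\n", x$saving_unemployed))
  invisible(x)
}
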