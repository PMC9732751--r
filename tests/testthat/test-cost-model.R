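params <- cost_parameters()

test_that("travel cost values the round trip and zeroes the telemedicine arm", {
  expect_equal(travel_cost(31.58, params, "control")$actual, 18.95,
               tolerance = 0.005 / 18.95)
  tele <- travel_cost(37.00, params, "telemedicine")
  expect_equal(tele$actual, 0)
  expect_equal(tele$counterfactual, 22.20, tolerance = 1e-10)
  expect_equal(travel_cost(0, params, "control")$actual, 0)
  expect_true(is.na(travel_cost(NA_real_, params, "control")$actual))
  expect_error(travel_cost(-1, params, "control"), "non-negative")
})

test_that("time cost applies the hourly rate per minute", {
  expect_equal(time_cost(154.80, params), 41.28)
  expect_equal(time_cost(36.88, params), 9.83, tolerance = 0.005 / 9.83)
  expect_equal(time_cost(2 * 34.80, params), 18.56)
  expect_equal(time_cost(60, params), 16.00)
  expect_error(time_cost(-10, params), "non-negative")
})

test_that("production loss per absence is one full working day", {
  expect_equal(round(production_loss_per_absence(params), 2), 205.18)
  expect_equal(round(production_loss_per_absence(
    cost_parameters(working_hours_per_day = 8.2)), 2), 241.74)
  expect_equal(round(production_loss_per_absence(
    cost_parameters(working_hours_per_day = 3.9)), 2), 114.97)
})

test_that("arm production loss totals and per-employed means match the trial", {
  tele <- arm_production_loss(1, 20, params)
  expect_equal(round(tele$total, 2), 205.18)
  expect_equal(round(tele$mean_per_employed, 2), 10.26)
  ctrl <- arm_production_loss(3, 19, params)
  expect_equal(round(ctrl$total, 2), 615.54)
  expect_equal(round(ctrl$mean_per_employed, 2), 32.40)
  none <- arm_production_loss(0, 19, params)
  expect_equal(none$total, 0)
  expect_equal(none$mean_per_employed, 0)
  expect_error(arm_production_loss(1, 0, params), "n_employed = 0")
  expect_error(arm_production_loss(5, 3, params), "n_absent")
})

test_that("per-employed SD of production loss matches the published sensitivity SDs", {
  full <- cost_parameters(working_hours_per_day = 8.2)
  part <- cost_parameters(working_hours_per_day = 3.9)
  expect_equal(round(arm_production_loss(1, 20, full)$sd_per_employed, 2), 54.05)
  expect_equal(round(arm_production_loss(3, 19, full)$sd_per_employed, 2), 90.56)
  expect_equal(round(arm_production_loss(1, 20, part)$sd_per_employed, 2), 25.71)
  expect_equal(round(arm_production_loss(3, 19, part)$sd_per_employed, 2), 43.07)
})

test_that("totals by employment status reproduce the published cost table", {
  ref <- reference_summary()
  tele <- arm_cost_summary(ref$telemedicine, params)
  ctrl <- arm_cost_summary(ref$control, params)
  expect_equal(total_cost_per_patient(tele, "employed"), 16.11)
  expect_equal(total_cost_per_patient(ctrl, "employed"), 92.63)
  expect_equal(total_cost_per_patient(tele, "unemployed"), 5.85)
  expect_equal(total_cost_per_patient(ctrl, "unemployed"), 60.23)
  # full-precision totals differ from the rounded-component sums by < 1 cent
  expect_lt(abs(total_cost_per_patient(ctrl, "employed", rounded = FALSE) - 92.63),
            0.01)
})

test_that("counterfactual avoided costs are reported but excluded from totals", {
  tele <- arm_cost_summary(reference_summary()$telemedicine, params)
  cf <- setNames(tele$components$counterfactual_mean, tele$components$component)
  expect_equal(round(cf[["travel_cost"]], 2), 22.20)
  expect_equal(round(cf[["travel_time_cost"]], 2), 20.51)
  expect_equal(tele$components$mean[tele$components$component == "travel_cost"], 0)
  # unemployed total contains only waiting-free composition: travel + total time
  expect_equal(total_cost_per_patient(tele, "unemployed", rounded = FALSE),
               5.845333, tolerance = 1e-6)
})

test_that("between-arm differences give the headline saving", {
  ref <- reference_summary()
  d <- cost_difference(arm_cost_summary(ref$telemedicine, params),
                       arm_cost_summary(ref$control, params))
  expect_equal(d$saving_employed, 76.52)
  tt <- d$components$difference[d$components$component == "total_time_cost"]
  expect_equal(round(tt, 2), 35.43)
  expect_error(
    cost_difference(
      arm_cost_summary(ref$telemedicine, cost_parameters(cost_per_km = 0.5)),
      arm_cost_summary(ref$control, params)
    ),
    "different cost parameters"
  )
})

test_that("identical arms with no travel produce zero differences", {
  coh <- mirror_cohort()
  d <- cost_difference(arm_cost_summary(coh, "telemedicine", params),
                       arm_cost_summary(coh, "control", params))
  expect_true(all(abs(d$components$difference) < 1e-12))
  expect_equal(d$saving_employed, 0)
  expect_equal(d$saving_unemployed, 0)
})

test_that("cost of the mean input equals the mean of per-patient costs (linearity)", {
  coh <- generate_cohort(cohort_config(n_per_arm = 30), seed = 9)
  for (arm in c("telemedicine", "control")) {
    via_patients <- arm_cost_summary(coh, arm, params)
    via_aggregate <- arm_cost_summary(aggregate_arm(coh, arm), params)
    expect_equal(via_patients$components$mean, via_aggregate$components$mean,
                 tolerance = 1e-12)
    expect_equal(via_patients$components$sd, via_aggregate$components$sd,
                 tolerance = 1e-12)
    expect_equal(via_patients$totals$total, via_aggregate$totals$total,
                 tolerance = 1e-12)
  }
})

test_that("cost SDs scale linearly with their inputs, matching the published SDs", {
  ctrl <- arm_cost_summary(reference_summary()$control, params)
  sds <- setNames(ctrl$components$sd, ctrl$components$component)
  expect_equal(round(sds[["travel_cost"]], 2), 13.57)       # 0.30 * 2 * 22.62
  expect_equal(round(sds[["travel_time_cost"]], 2), 11.14)  # 16/60 * 2 * 20.89
  expect_equal(round(sds[["waiting_time_cost"]], 2), 7.34)  # 16/60 * 27.54
  expect_equal(round(sds[["total_time_cost"]], 2), 21.27)   # 16/60 * 79.75
})

test_that("totals are non-decreasing in every unit cost parameter", {
  ref <- reference_summary()$control
  base <- total_cost_per_patient(arm_cost_summary(ref, params), "employed",
                                 rounded = FALSE)
  for (key in c("cost_per_km", "time_value_per_hour", "gross_hourly_wage",
                "working_hours_per_day")) {
    args <- as.list(unclass(params))
    args[[key]] <- args[[key]] * 1.5
    up <- total_cost_per_patient(arm_cost_summary(ref, do.call(cost_parameters, args)),
                                 "employed", rounded = FALSE)
    expect_gte(up, base)
  }
})

test_that("telemedicine actual travel costs are zero for any parameters", {
  ref <- reference_summary()$telemedicine
  for (ckm in c(0.1, 1, 10)) {
    s <- arm_cost_summary(ref, cost_parameters(cost_per_km = ckm))
    expect_equal(s$components$mean[s$components$component == "travel_cost"], 0)
    expect_equal(s$components$mean[s$components$component == "travel_time_cost"], 0)
  }
})

test_that("per-patient cost table propagates missing items", {
  coh <- toy_cohort()
  coh$one_way_distance_km[4] <- NA
  coh$absent_from_work[1] <- NA
  pc <- patient_costs(coh, params)
  expect_true(is.na(pc$travel_cost[4]))
  expect_true(is.na(pc$total_cost_unemployed_basis[4]))
  expect_true(is.na(pc$production_loss[1]))
  # telemedicine actuals are zero, counterfactuals priced
  expect_equal(pc$travel_cost[1:3], c(0, 0, 0))
  expect_equal(pc$travel_cost_counterfactual[2], 0.30 * 2 * 50)
  expect_equal(pc$total_cost_unemployed_basis[5],
               0.30 * 2 * 40 + 16 * 180 / 60)
})
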