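base_report <- run_base_case(reference_summary())

test_that("the base case reproduces the headline numbers", {
  expect_equal(base_report$difference$saving_employed, 76.52)
  expect_equal(round(base_report$emissions$per_patient$masses_kg[["greenhouse_gases"]], 3),
               11.248)
  t3 <- base_report$table3
  expect_equal(t3$difference[t3$component == "Travel costs"], 18.95)
  expect_equal(t3$difference[t3$component == "Production loss"], 410.36)
})

test_that("a cohort with both arms identical and no travel yields zero differences", {
  rep0 <- run_base_case(mirror_cohort())
  expect_true(all(abs(rep0$table3$difference) < 1e-12))
  expect_equal(rep0$difference$saving_employed, 0)
  expect_false(is.null(rep0$table1))
})

test_that("a single-arm cohort is rejected", {
  only_tele <- toy_cohort()[1:3, ]
  expect_error(run_base_case(only_tele), "both arms")
})

test_that("patient-level input adds demographic and p-value columns", {
  coh <- generate_cohort(cohort_config(), seed = 31)
  rep <- run_base_case(coh)
  expect_false(is.null(rep$table1))
  expect_true(all(c("indication", "age_band", "sex", "employed") %in%
                    rep$table1$characteristic))
  expect_true(all(rep$table1$p_value >= 0 & rep$table1$p_value <= 1))
  expect_true(all(rep$table2$p_value >= 0 & rep$table2$p_value <= 1))
  # aggregate input carries no p-values
  expect_true(all(is.na(base_report$table2$p_value)))
})

test_that("employment scenarios change only production-loss-derived cells", {
  res <- run_scenarios(base_report, default_scenarios())
  for (nm in c("full_time", "part_time")) {
    sc <- res[[nm]]
    expect_null(sc$table4)  # emission tables untouched by cost scenarios
    keep <- sc$table3$component != "Production loss"
    expect_equal(sc$table3[keep, ], base_report$table3[keep, ])
  }
  expect_equal(total_in(res$full_time, "telemedicine", "employed"), 17.94)
  expect_equal(total_in(res$full_time, "control", "employed"), 98.40)
  expect_equal(total_in(res$part_time, "telemedicine", "employed"), 11.60)
  expect_equal(total_in(res$part_time, "control", "employed"), 78.38)
})

test_that("savings across the employment scenarios span the published range", {
  res <- run_scenarios(base_report, default_scenarios())
  savings <- c(
    base_report$difference$saving_employed,
    res$full_time$difference$saving_employed,
    res$part_time$difference$saving_employed
  )
  expect_equal(min(savings), 66.78)
  expect_equal(max(savings), 80.46)
})

test_that("the carbon-price scenario leaves the cost table untouched", {
  res <- run_scenarios(base_report, default_scenarios())
  carbon <- res$equal_weight_carbon
  expect_null(carbon$table3)
  expect_null(carbon$totals)
  expect_equal(round(carbon$emissions$per_patient$env_cost, 2), 9.53)
  expect_equal(round(carbon$emissions$total$env_cost, 2), 247.91)
  # emission masses do not depend on the carbon price
  expect_equal(carbon$emissions$per_patient$masses_kg,
               base_report$emissions$per_patient$masses_kg)
})

test_that("the doubled-volume scenario doubles the annual table exactly", {
  res <- run_scenarios(base_report, default_scenarios())
  s16 <- res$sixteen_per_week
  expect_null(s16$table3)
  expect_null(s16$table4)
  expect_identical(s16$annual$masses_kg, 2 * base_report$annual$masses_kg)
  expect_identical(s16$annual$env_cost, 2 * base_report$annual$env_cost)
})

test_that("unknown scenario keys error listing the valid ones", {
  expect_error(scenario("bad", petrol_price = 2), "unknown scenario override")
  expect_error(scenario("bad", petrol_price = 2), "valid keys")
  expect_equal(run_scenarios(base_report, list()), list())
})

test_that("rendering is deterministic and carries the report content", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  scen <- run_scenarios(base_report, default_scenarios())
  f1 <- render_report(base_report, dir1, "csv", scenarios = scen)
  f2 <- render_report(base_report, dir2, "csv", scenarios = scen)
  expect_setequal(basename(f1), basename(f2))
  for (nm in basename(f1)) {
    expect_identical(readLines(file.path(dir1, nm)),
                     readLines(file.path(dir2, nm)),
                     label = nm)
  }
  t3 <- read.csv(file.path(dir1, "table3.csv"))
  row <- t3[t3$component == "Travel costs", ]
  expect_equal(row$difference, 18.95)
  expect_equal(row$difference_usd, round(18.95 * 0.97, 2))
  expect_true(file.exists(file.path(dir1, "metadata.yml")))
  meta <- yaml::read_yaml(file.path(dir1, "metadata.yml"))
  expect_equal(meta$params$cost_per_km, 0.30)
})

test_that("markdown rendering produces readable tables with units", {
  dir <- withr::local_tempdir()
  render_report(base_report, dir, "markdown")
  md <- readLines(file.path(dir, "report.md"))
  expect_true(any(grepl("^\\| ", md)))
  expect_true(any(grepl("EUR", md)))
  expect_true(any(grepl("kg", md)))
})

test_that("end-to-end runs are deterministic for identical input", {
  coh <- generate_cohort(cohort_config(), seed = 12)
  r1 <- run_base_case(coh)
  r2 <- run_base_case(coh)
  r1$metadata$version <- r2$metadata$version <- NULL
  expect_equal(r1[c("table2", "table3", "table4", "totals")],
               r2[c("table2", "table3", "table4", "totals")])
})
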