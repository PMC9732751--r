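test_that("write/read round trip is the identity on a generated cohort", {
  coh <- generate_cohort(cohort_config(), seed = 11)
  expect_equal(nrow(coh), 52L)
  expect_equal(unname(table(coh$arm)[c("telemedicine", "control")]),
               c(26L, 26L), ignore_attr = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
})

test_that("a header-only file yields an empty cohort with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(toy_cohort()[0, ], path)
  expect_warning(coh <- read_cohort(path), "no data rows")
  expect_equal(nrow(coh), 0L)
})

test_that("blank optional cells become missing values", {
  coh <- toy_cohort()
  coh$employed[2] <- NA
  coh$absent_from_work[2] <- NA
  coh$one_way_distance_km[4] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_true(is.na(back$employed[2]))
  expect_true(is.na(back$one_way_distance_km[4]))
})

test_that("malformed and invalid rows are rejected with row addresses", {
  path <- withr::local_tempfile(fileext = ".csv")

  coh <- toy_cohort()
  write_cohort(coh, path)
  txt <- readLines(path)
  txt[2] <- sub("30,30", "3O,30", txt[2])  # corrupt distance of row 1
  writeLines(txt, path)
  expect_error(read_cohort(path), "malformed numeric.*row 1")

  bad_arm <- toy_cohort()
  bad_arm$arm[3] <- "placebo"
  expect_error(validate_cohort(bad_arm), "unknown arm.*row 3")

  neg <- toy_cohort()
  neg$waiting_time_min[2] <- -5
  expect_error(validate_cohort(neg), "negative.*waiting_time_min.*row 2")

  orphan <- toy_cohort()
  orphan$employed[1] <- FALSE
  orphan$absent_from_work[1] <- TRUE
  expect_error(validate_cohort(orphan), "absent_from_work.*row 1")
})

test_that("aggregate_arm computes per-variable statistics over non-missing values", {
  coh <- toy_cohort()
  coh$waiting_time_min <- c(2, 4, 6, 10, NA, 30)
  agg <- aggregate_arm(coh, "telemedicine")
  w <- agg$stats[agg$stats$variable == "waiting_time_min", ]
  expect_equal(w$mean, 4)
  expect_equal(w$sd, 2)  # sample SD, n - 1 denominator
  expect_equal(w$n, 3L)
  # control arm: one waiting value missing, denominator drops to 2
  aggc <- aggregate_arm(coh, "control")
  wc <- aggc$stats[aggc$stats$variable == "waiting_time_min", ]
  expect_equal(wc$n, 2L)
  expect_equal(wc$mean, 20)
  expect_equal(aggc$n_records, 3L)
})

test_that("a single record gives mean equal to the value and SD zero", {
  one <- toy_record("T01", "telemedicine", distance = 10)
  agg <- aggregate_arm(one, "telemedicine")
  d <- agg$stats[agg$stats$variable == "one_way_distance_km", ]
  expect_equal(d$mean, 10)
  expect_equal(d$sd, 0)
})

test_that("aggregation is invariant to record order and to the other arm", {
  coh <- generate_cohort(cohort_config(n_per_arm = 15), seed = 5)
  base <- aggregate_arm(coh, "control")
  shuffled <- coh[rev(seq_len(nrow(coh))), ]
  expect_equal(aggregate_arm(shuffled, "control")$stats, base$stats)
  only_control <- coh[coh$arm == "control", ]
  expect_equal(aggregate_arm(only_control, "control")$stats, base$stats)
})

test_that("an arm with zero records errors naming the arm", {
  only_tele <- toy_cohort()[1:3, ]
  expect_error(aggregate_arm(only_tele, "control"), "control")
})

test_that("quartiles use linear interpolation between order statistics", {
  coh <- toy_record("C01", "control", waiting = 1)
  for (w in c(2, 3, 4)) {
    coh <- rbind(coh, toy_record(paste0("C0", w), "control", waiting = w))
  }
  agg <- aggregate_arm(coh, "control")
  q <- agg$stats[agg$stats$variable == "waiting_time_min", ]
  expect_equal(c(q$q1, q$median, q$q3), c(1.75, 2.5, 3.25))
})

test_that("parameter files resolve to defaults when empty and reject unknown keys", {
  empty <- withr::local_tempfile(fileext = ".yml")
  writeLines("", empty)
  cfg <- read_params(empty)
  expect_equal(cfg$cost$cost_per_km, 0.30)
  expect_equal(cfg$emission$env_cost_per_pkm, 0.05045)
  expect_equal(read_params(NULL)$cost$time_value_per_hour, 16)

  cfgfile <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("cost:", "  working_hours_per_day: 8.2"), cfgfile)
  expect_equal(read_params(cfgfile)$cost$working_hours_per_day, 8.2)

  badfile <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("cost:", "  price_per_mile: 1"), badfile)
  expect_error(read_params(badfile), "unknown cost parameter.*valid keys")
})
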