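# hand-built miniature cohorts with known values

toy_record <- function(patient_id, arm, distance = 10, travel = 20,
                       waiting = 10, treatment = 10, total = 60,
                       employed = TRUE, absent = FALSE, mode = "car",
                       indication = "knee", age_band = "41-60",
                       sex = "female") {
  tibble::tibble(
    patient_id = patient_id, arm = arm, indication = indication,
    age_band = age_band, sex = sex, employed = employed,
    one_way_distance_km = distance, travel_time_min = travel,
    waiting_time_min = waiting, treatment_duration_min = treatment,
    total_time_min = total, absent_from_work = absent,
    transport_mode = mode
  )
}

toy_cohort <- function() {
  rbind(
    toy_record("T01", "telemedicine", distance = 30, travel = 30, waiting = 5,
               treatment = 8, total = 20),
    toy_record("T02", "telemedicine", distance = 50, travel = 45, waiting = 10,
               treatment = 10, total = 30, absent = TRUE),
    toy_record("T03", "telemedicine", distance = 10, travel = 15, waiting = 3,
               treatment = 6, total = 15, employed = FALSE),
    toy_record("C01", "control", distance = 20, travel = 25, waiting = 30,
               treatment = 10, total = 120),
    toy_record("C02", "control", distance = 40, travel = 50, waiting = 45,
               treatment = 12, total = 180, absent = TRUE),
    toy_record("C03", "control", distance = 25, travel = 30, waiting = 20,
               treatment = 9, total = 140, employed = FALSE)
  )
}

total_in <- function(res, arm, employment) {
  res$totals$total_rounded_components[res$totals$arm == arm &
                                        res$totals$employment == employment]
}

# two arms with identical inputs and no travel: every between-arm cost
# difference must vanish
mirror_cohort <- function() {
  rows <- lapply(1:4, function(i) {
    rbind(
      toy_record(sprintf("T%02d", i), "telemedicine", distance = 0, travel = 0,
                 waiting = 10 * i, treatment = 5 + i, total = 30 + 5 * i,
                 employed = i < 4, absent = i == 1),
      toy_record(sprintf("C%02d", i), "control", distance = 0, travel = 0,
                 waiting = 10 * i, treatment = 5 + i, total = 30 + 5 * i,
                 employed = i < 4, absent = i == 1)
    )
  })
  do.call(rbind, rows)
}
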