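#' @keywords internal
.arms <- c("telemedicine", "control")
.indications <- c("knee", "shoulder")
.age_bands <- c("18-40", "41-60", ">60")
.sexes <- c("female", "male")
.transport_modes <- c("car", "public_transport")

# continuous questionnaire items, in reporting order
.cohort_variables <- c(
  "treatment_duration_min",
  "one_way_distance_km",
  "travel_time_min",
  "waiting_time_min",
  "total_time_min"
)

.cohort_columns <- c(
  "patient_id", "arm", "indication", "age_band", "sex", "employed",
  "one_way_distance_km", "travel_time_min", "waiting_time_min",
  "treatment_duration_min", "total_time_min", "absent_from_work",
  "transport_mode"
)

#' Validate a patient-level cohort
#'
#' Checks a cohort against the questionnaire-record contract: required
#' categorical fields present with known labels, distances and times
#' non-negative where recorded, and a work absence only recorded for
#' employed patients. Distances are stored one-way; round-trip doubling
#' happens inside the cost and emission operations. For telemedicine
#' records the distance and travel time are the hypothetical values the
#' patient would have faced travelling to the clinic.
#'
#' @param cohort A data frame with the cohort columns (see [read_cohort()]).
#' @return The validated cohort as a tibble, invisibly usable downstream.
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cohort <- cohort[.cohort_columns]

  fail_rows <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      stop(msg, " (row ", paste(which(bad), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  check_enum <- function(col, levels, required = TRUE) {
    v <- cohort[[col]]
    if (required) fail_rows(is.na(v), paste0("missing required field '", col, "'"))
    fail_rows(!is.na(v) & !(v %in% levels),
              paste0("unknown ", col, " label; expected one of: ",
                     paste(levels, collapse = ", ")))
  }
  check_enum("arm", .arms)
  check_enum("indication", .indications)
  check_enum("age_band", .age_bands)
  check_enum("sex", .sexes)
  check_enum("transport_mode", .transport_modes, required = FALSE)
  cohort$transport_mode[is.na(cohort$transport_mode)] <- "car"

  for (col in .cohort_variables) {
    v <- cohort[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    fail_rows(!is.na(v) & (v < 0 | !is.finite(v)),
              paste0("negative or non-finite value in '", col, "'"))
  }
  for (col in c("employed", "absent_from_work")) {
    if (!is.logical(cohort[[col]])) {
      stop("column '", col, "' must be logical (TRUE/FALSE or blank)",
           call. = FALSE)
    }
  }
  fail_rows(!is.na(cohort$absent_from_work) & cohort$absent_from_work &
              (is.na(cohort$employed) | !cohort$employed),
            "absent_from_work recorded TRUE for a patient not known to be employed")
  cohort
}

#' Read a patient-level cohort from CSV
#'
#' Reads a two-arm questionnaire cohort from a UTF-8, comma-separated file
#' with a header row and "." as decimal mark. Blank cells become missing
#' optionals; rows are validated (labels, non-negativity, absence implies
#' employment) with row-addressed errors. A header-only file yields an
#' empty cohort with a warning.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort tibble, one row per patient.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols)) {
    stop("cohort header is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("cohort file has a header but no data rows: ", path, call. = FALSE)
    return(validate_cohort(empty_cohort()))
  }
  parse_num <- function(col) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(out)
    if (any(bad)) {
      stop("malformed numeric value '", v[which(bad)[1]], "' in column '",
           col, "' (row ", which(bad)[1], ")", call. = FALSE)
    }
    out
  }
  parse_bool <- function(col) {
    v <- tolower(raw[[col]])
    out <- rep(NA, length(v))
    out[v %in% c("true", "t", "1", "yes")] <- TRUE
    out[v %in% c("false", "f", "0", "no")] <- FALSE
    bad <- !is.na(v) & is.na(out)
    if (any(bad)) {
      stop("malformed logical value '", raw[[col]][which(bad)[1]],
           "' in column '", col, "' (row ", which(bad)[1], ")", call. = FALSE)
    }
    out
  }
  cohort <- tibble(
    patient_id = raw$patient_id,
    arm = raw$arm,
    indication = raw$indication,
    age_band = raw$age_band,
    sex = raw$sex,
    employed = parse_bool("employed"),
    one_way_distance_km = parse_num("one_way_distance_km"),
    travel_time_min = parse_num("travel_time_min"),
    waiting_time_min = parse_num("waiting_time_min"),
    treatment_duration_min = parse_num("treatment_duration_min"),
    total_time_min = parse_num("total_time_min"),
    absent_from_work = parse_bool("absent_from_work"),
    transport_mode = raw$transport_mode
  )
  validate_cohort(cohort)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: UTF-8, comma-separated, "." decimal mark,
#' header row, blank cells for missing optionals. Round-tripping a
#' validated cohort through `write_cohort()` then [read_cohort()] is the
#' identity.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- as.data.frame(cohort)
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

empty_cohort <- function() {
  tibble(
    patient_id = character(), arm = character(), indication = character(),
    age_band = character(), sex = character(), employed = logical(),
    one_way_distance_km = numeric(), travel_time_min = numeric(),
    waiting_time_min = numeric(), treatment_duration_min = numeric(),
    total_time_min = numeric(), absent_from_work = logical(),
    transport_mode = character()
  )
}

#' Construct an arm-level aggregate directly
#'
#' Builds the summary container used by the linear cost and emission models:
#' per-variable n / mean / SD / median / quartiles plus employment and
#' absence counts. Normally produced by [aggregate_arm()] or
#' [reference_summary()]; exposed so published group summaries can be fed
#' to the models without patient-level data.
#'
#' @param arm `"telemedicine"` or `"control"`.
#' @param n_records Number of patients in the arm.
#' @param stats Tibble with columns `variable`, `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, one row per continuous questionnaire item.
#' @param n_employed Number of patients known to be employed.
#' @param n_employment_known Denominator for the employment proportion
#'   (patients who answered the employment item).
#' @param n_absent Number of employed patients absent from work.
#' @return An object of class `arm_aggregate`.
#' @export
arm_aggregate <- function(arm, n_records, stats, n_employed,
                          n_employment_known, n_absent) {
  arm <- match.arg(arm, .arms)
  stats <- as_tibble(stats)
  need <- c("variable", "n", "mean", "sd", "median", "q1", "q3")
  if (!all(need %in% names(stats))) {
    stop("aggregate stats need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(stats$n > n_records)) {
    stop("per-variable n cannot exceed the number of records", call. = FALSE)
  }
  if (any(stats$sd < 0, na.rm = TRUE)) stop("SD must be >= 0", call. = FALSE)
  if (n_absent > n_employed) {
    stop("n_absent cannot exceed n_employed", call. = FALSE)
  }
  if (n_employed > n_employment_known || n_employment_known > n_records) {
    stop("employment counts inconsistent with n_records", call. = FALSE)
  }
  structure(
    list(
      arm = arm, n_records = n_records, stats = stats,
      n_employed = n_employed, n_employment_known = n_employment_known,
      n_absent = n_absent
    ),
    class = "arm_aggregate"
  )
}

agg_stat <- function(agg, variable, field = "mean") {
  row <- match(variable, agg$stats$variable)
  if (is.na(row)) stop("no aggregate for variable '", variable, "'", call. = FALSE)
  agg$stats[[field]][row]
}

#' Summarize one trial arm
#'
#' Computes, for each continuous questionnaire item, the count of
#' non-missing responses, mean, sample SD (n-1 denominator), median and
#' quartiles (linear interpolation between order statistics), plus
#' employment and work-absence counts. Missing items are excluded per
#' variable, never by whole-record deletion, so the per-variable
#' denominators may differ.
#'
#' @param cohort A validated cohort tibble (may contain both arms).
#' @param arm Which arm to summarize.
#' @return An [arm_aggregate()] object.
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_arm = 10), seed = 1)
#' aggregate_arm(coh, "control")
#' @export
aggregate_arm <- function(cohort, arm = .arms) {
  arm <- match.arg(arm)
  cohort <- validate_cohort(cohort)
  sub <- cohort[cohort$arm == arm, ]
  if (nrow(sub) == 0L) {
    stop("no records in arm '", arm, "'", call. = FALSE)
  }
  stats <- do.call(rbind, lapply(.cohort_variables, function(v) {
    x <- sub[[v]]
    x <- x[!is.na(x)]
    qs <- if (length(x)) unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
          else rep(NA_real_, 3)
    tibble(
      variable = v, n = length(x),
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else if (length(x) == 1) 0 else NA_real_,
      median = qs[2], q1 = qs[1], q3 = qs[3]
    )
  }))
  arm_aggregate(
    arm = arm,
    n_records = nrow(sub),
    stats = stats,
    n_employed = sum(sub$employed, na.rm = TRUE),
    n_employment_known = sum(!is.na(sub$employed)),
    n_absent = sum(sub$absent_from_work, na.rm = TRUE)
  )
}

#' @export
print.arm_aggregate <- function(x, ...) {
  cat(sprintf("Arm aggregate: %s (n = %d)\n", x$arm, x$n_records))
  df <- as.data.frame(x$stats)
  df[-1] <- lapply(df[-1], function(v) round(v, 2))
  print(df, row.names = FALSE)
  cat(sprintf("  employed: %d / %d; absent from work: %d\n",
              x$n_employed, x$n_employment_known, x$n_absent))
  invisible(x)
}
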