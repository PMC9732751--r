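#' Write report tables to disk
#'
#' Renders an [run_base_case()] report (and optionally its
#' [run_scenarios()] results) to a directory, either as one CSV per table
#' or as a single markdown document. Numbers in the primary tables are at
#' reporting precision (cents for euros; three decimals for kg, four for
#' per-patient particulates); full-precision companions (`*_full.csv`) are
#' written alongside, and run metadata (parameters, version) goes to
#' `metadata.yml`. Rendering is deterministic: the same report yields
#' byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory, created if needed.
#' @param format `"csv"` or `"markdown"`.
#' @param scenarios Optional list of `scenario_result`s to include.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, out_dir, format = c("csv", "markdown"),
                          scenarios = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  tables <- report_tables(report, scenarios)
  paths <- if (format == "csv") {
    render_csv(tables, out_dir)
  } else {
    render_markdown(tables, out_dir)
  }
  meta_path <- file.path(out_dir, "metadata.yml")
  yaml::write_yaml(report$metadata, meta_path)
  invisible(c(paths, meta_path))
}

round_cols <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

report_tables <- function(report, scenarios) {
  out <- list()
  if (!is.null(report$table1)) {
    t1 <- report$table1
    t1$p_value <- format_p(t1$p_value)
    out$table1 <- t1
  }
  t2 <- report$table2
  num <- vapply(t2, is.numeric, logical(1))
  t2[num] <- lapply(t2[num], round, digits = 2)
  t2$p_value <- format_p(report$table2$p_value)
  out$table2 <- t2

  out$table3 <- round_cols(report$table3, 2)
  out$table3_full <- report$table3
  usd <- report$metadata$params$eur_to_usd
  out$table3$difference_usd <- round(out$table3$difference * usd, 2)

  t4 <- report$table4
  t4r <- t4
  t4r$per_patient <- ifelse(
    t4$quantity == "particulates", round(t4$per_patient, 4),
    ifelse(t4$quantity == "environmental_cost_eur",
           round(t4$per_patient, 2), round(t4$per_patient, 3)))
  t4r$total <- ifelse(t4$quantity == "environmental_cost_eur",
                      round(t4$total, 2), round(t4$total, 3))
  out$table4 <- t4r
  out$table4_full <- t4

  ann <- report$annual
  out$annual <- tibble(
    quantity = c(names(ann$masses_kg), "environmental_cost_eur", "pkm",
                 "annual_patients"),
    value = c(round(unname(ann$masses_kg), 2), round(ann$env_cost, 2),
              round(ann$pkm, 1), ann$n_patients)
  )
  out$totals <- round_cols(report$totals, 2)

  if (!is.null(scenarios) && length(scenarios)) {
    out$scenarios <- do.call(rbind, lapply(scenarios, scenario_long))
  }
  out
}

scenario_long <- function(res) {
  rows <- list()
  if (!is.null(res$totals)) {
    rows <- c(rows, list(tibble(
      scenario = res$name,
      quantity = paste0("total_", res$totals$arm, "_", res$totals$employment),
      value = round(res$totals$total_rounded_components, 2)
    ), tibble(
      scenario = res$name,
      quantity = c("saving_employed", "saving_unemployed"),
      value = c(res$difference$saving_employed, res$difference$saving_unemployed)
    )))
  }
  if (!is.null(res$emissions)) {
    rows <- c(rows, list(tibble(
      scenario = res$name,
      quantity = c("env_cost_per_patient", "env_cost_total"),
      value = round(c(res$emissions$per_patient$env_cost,
                      res$emissions$total$env_cost), 2)
    )))
  }
  if (!is.null(res$annual)) {
    rows <- c(rows, list(tibble(
      scenario = res$name,
      quantity = c(paste0("annual_", names(res$annual$masses_kg), "_kg"),
                   "annual_env_cost_eur"),
      value = round(c(unname(res$annual$masses_kg), res$annual$env_cost), 2)
    )))
  }
  do.call(rbind, rows)
}

render_csv <- function(tables, out_dir) {
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  paths
}

md_table <- function(df) {
  df <- as.data.frame(df)
  cells <- lapply(df, function(col) {
    if (is.numeric(col)) {
      out <- vapply(col, function(v) {
        if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE)
      }, character(1))
    } else {
      out <- ifelse(is.na(col), "", as.character(col))
    }
    out
  })
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(do.call(cbind, cells), 1, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(header, sep, body)
}

render_markdown <- function(tables, out_dir) {
  titles <- c(
    table1 = "Demographic characteristics",
    table2 = "Questionnaire variables (minutes / km)",
    table3 = "Costs per appointment (EUR, reporting precision)",
    table3_full = "Costs per appointment (EUR, full precision)",
    table4 = "Avoided emissions (kg) and environmental costs (EUR), telemedicine arm",
    table4_full = "Avoided emissions and environmental costs (full precision)",
    annual = "Annual extrapolation",
    totals = "Totals by employment status (EUR)",
    scenarios = "Sensitivity scenarios"
  )
  lines <- c("# Societal-perspective analysis report", "")
  for (nm in names(tables)) {
    lines <- c(lines, paste0("## ", titles[[nm]]), "", md_table(tables[[nm]]), "")
  }
  p <- file.path(out_dir, "report.md")
  writeLines(lines, p)
  p
}
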